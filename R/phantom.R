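#' Default 511 keV linear attenuation coefficients (1/mm)
#'
#' Literature-standard tissue values used throughout the package: air 0,
#' soft tissue (water-like) 0.0096, fat 0.0090, cranial bone 0.0151, and the
#' single bone class assigned by the UTE-like degradation 0.0110. All are
#' configurable wherever they are used.
#' @export
tissue_mu_defaults <- function() {
  c(air = 0, soft = 0.0096, fat = 0.0090, bone = 0.0151, ute_bone = 0.0110)
}

#' Generate a digital brain-like phantom
#'
#' Builds the synthetic stand-in for a tri-modality (PET/MRI/CT) patient
#' dataset: an activity image, an integer label atlas with named regions, and
#' a ground-truth CT-derived attenuation map, all on one grid centred on the
#' world origin. The head is parametric, not anatomical: concentric
#' cylindrical shells (outer air, scalp soft tissue, skull bone) around a
#' brain disc that is partitioned angularly into a cortical annulus (regions
#' flagged `near_skull`) and an interior core (subcortical regions). Activity
#' is a uniform grey-matter background with seeded per-region multiplicative
#' perturbations of +/-10%; skull and air carry no activity.
#'
#' @param seed integer; drives the per-region activity perturbations (the
#'   atlas geometry is deterministic).
#' @param grid integer length-3 `(nx, ny, nz)`, each >= 32.
#' @param spacing voxel size in mm.
#' @param n_rois number of brain regions (>= 4); split half cortical, half
#'   subcortical.
#' @param radii named vector (mm): `brain`, `skull_outer`, `scalp_outer`.
#'   The grid must contain the scalp shell or the call is rejected.
#' @param activity_background grey-matter background activity (Bq/mL).
#' @param scalp_activity_fraction scalp activity as a fraction of background.
#' @return a `phantom_bundle`: list with `activity`, `atlas`, `mu_ct`
#'   (`voxel_volume`s on one grid), `labels` (data.frame `id`, `name`,
#'   `near_skull`), and `seed`.
#' @export
generate_phantom <- function(seed = 1L, grid = c(128, 128, 16),
                             spacing = c(2, 2, 2), n_rois = 8L,
                             radii = c(brain = 78, skull_outer = 86,
                                       scalp_outer = 92),
                             activity_background = 5000,
                             scalp_activity_fraction = 0.25) {
  grid <- as.integer(grid)
  if (length(grid) != 3L || any(grid[1:2] < 32L) || grid[3] < 4L)
    stop("grid must be (nx, ny, nz) with nx, ny >= 32 and nz >= 4")
  if (n_rois < 4L) stop("n_rois must be >= 4")
  r_brain <- radii[["brain"]]
  r_skull <- radii[["skull_outer"]]
  r_scalp <- radii[["scalp_outer"]]
  if (!(0 < r_brain && r_brain < r_skull && r_skull < r_scalp))
    stop("radii must satisfy 0 < brain < skull_outer < scalp_outer")
  half_extent <- min((grid[1:2] - 1) / 2 * spacing[1:2])
  if (half_extent < r_scalp)
    stop(sprintf(paste0("grid too small to contain the three shells: ",
                        "transaxial half-extent %.1f mm < scalp radius ",
                        "%.1f mm; enlarge the grid or shrink 'radii'"),
                 half_extent, r_scalp))

  origin <- -(grid - 1) / 2 * spacing
  xs <- origin[1] + (seq_len(grid[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(grid[2]) - 1) * spacing[2]
  r2 <- outer(xs^2, ys^2, `+`)
  r <- sqrt(r2)
  theta <- atan2(rep(ys, each = grid[1]), rep(xs, times = grid[2])) %% (2 * pi)
  dim(theta) <- grid[1:2]

  # Angular partition: cortical annulus hugging the skull vs interior core.
  n_cort <- as.integer(ceiling(n_rois / 2))
  n_core <- as.integer(n_rois) - n_cort
  r_core <- 0.6 * r_brain
  slab <- matrix(0L, grid[1], grid[2])
  slab[r <= r_scalp] <- 1L                       # scalp
  slab[r <= r_skull] <- 2L                       # skull
  cort_idx <- pmin(floor(theta / (2 * pi / n_cort)), n_cort - 1)
  core_idx <- pmin(floor(theta / (2 * pi / n_core)), n_core - 1)
  in_cort <- r <= r_brain & r > r_core
  in_core <- r <= r_core
  slab[in_cort] <- 3L + cort_idx[in_cort]
  slab[in_core] <- 3L + n_cort + core_idx[in_core]
  atlas_data <- array(slab, grid)

  labels <- data.frame(
    id = 0:(2L + n_rois),
    name = c("air", "scalp", "skull",
             roi_names(n_cort, cortical = TRUE),
             roi_names(n_core, cortical = FALSE)),
    near_skull = c(NA, NA, NA, rep(TRUE, n_cort), rep(FALSE, n_core)),
    stringsAsFactors = FALSE)

  mu <- tissue_mu_defaults()
  mu_data <- array(0, grid)
  mu_data[atlas_data == 1L] <- mu[["soft"]]
  mu_data[atlas_data == 2L] <- mu[["bone"]]
  mu_data[atlas_data >= 3L] <- mu[["soft"]]

  perturb <- with_seed(seed, stats::runif(n_rois, -0.1, 0.1))
  act_data <- array(0, grid)
  act_data[atlas_data == 1L] <- scalp_activity_fraction * activity_background
  for (k in seq_len(n_rois)) {
    act_data[atlas_data == 2L + k] <- activity_background * (1 + perturb[k])
  }

  structure(list(
    activity = voxel_volume(act_data, spacing, origin, kind = "activity"),
    atlas = voxel_volume(atlas_data, spacing, origin, kind = "label"),
    labels = labels,
    mu_ct = voxel_volume(mu_data, spacing, origin, kind = "mu"),
    seed = as.integer(seed)),
    class = "phantom_bundle")
}

roi_names <- function(n, cortical) {
  base <- if (cortical) {
    c("superior_frontal_cortex", "parietal_cortex", "temporal_cortex",
      "occipital_cortex")
  } else {
    c("thalamus", "putamen", "caudate", "white_matter")
  }
  extra <- if (n > length(base)) {
    sprintf("%s_%d", if (cortical) "cortical" else "subcortical",
            seq.int(length(base) + 1, n))
  } else character(0)
  c(base[seq_len(min(n, length(base)))], extra)
}

#' @export
print.phantom_bundle <- function(x, ...) {
  cat(sprintf("<phantom_bundle> seed %d, %d brain ROIs, grid %s @ %s mm\n",
              x$seed, sum(x$labels$id >= 3),
              paste(dim(x$atlas$data), collapse = "x"),
              paste(x$atlas$spacing, collapse = "x")))
  invisible(x)
}

#' MRAC variant specifications
#'
#' Describes one attenuation-map degradation emulating the behaviour of an
#' MR-based attenuation correction method relative to the ground-truth CT
#' map; consumed by [derive_mrac()]. `CTAC` is the identity (the reference).
#'
#' @param name `"CTAC"`, `"DIXON"`, `"DIXONBONE"`, `"UTE"` or `"DLDIXON"`.
#' @param ... per-variant parameter overrides: `mu_soft`, and
#'   `bone_scale`, `erosion_voxels` (DIXONBONE); `bone_mu`, `flip_fraction`
#'   (UTE); `noise_sigma_frac` (DLDIXON).
#' @return an object of class `mrac_variant`.
#' @export
mrac_variant <- function(name = c("CTAC", "DIXON", "DIXONBONE", "UTE",
                                  "DLDIXON"), ...) {
  name <- match.arg(toupper(name), c("CTAC", "DIXON", "DIXONBONE", "UTE",
                                     "DLDIXON"))
  mu <- tissue_mu_defaults()
  params <- switch(name,
    CTAC = list(),
    DIXON = list(mu_soft = mu[["soft"]]),
    DIXONBONE = list(mu_soft = mu[["soft"]], bone_scale = 0.95,
                     erosion_voxels = 1L),
    UTE = list(mu_soft = mu[["soft"]], bone_mu = mu[["ute_bone"]],
               flip_fraction = 0.20),
    DLDIXON = list(mu_soft = mu[["soft"]], noise_sigma_frac = 0.01))
  override <- list(...)
  bad <- setdiff(names(override), names(params))
  if (length(bad))
    stop("unknown parameter(s) for variant ", name, ": ",
         paste(bad, collapse = ", "))
  params[names(override)] <- override
  structure(list(name = name, parameters = params), class = "mrac_variant")
}

#' @export
print.mrac_variant <- function(x, ...) {
  cat(sprintf("<mrac_variant> %s", x$name))
  if (length(x$parameters))
    cat(" (", paste(names(x$parameters), unlist(x$parameters), sep = "=",
                    collapse = ", "), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Derive an MRAC-like attenuation map from the ground truth
#'
#' Applies one of four degradation operators to the CT-derived mu-map,
#' emulating how each MR-based attenuation map misrepresents bone:
#' \describe{
#'   \item{DIXON}{bone invisible to the two-point Dixon segmentation: every
#'     skull-label voxel is replaced by soft-tissue mu.}
#'   \item{DIXONBONE}{model-based bone retained but imperfect: skull mu
#'     scaled by `bone_scale` (default 0.95) after a 1-voxel morphological
#'     erosion of the skull (eroded voxels fall back to soft tissue).}
#'   \item{UTE}{two-compartment segmentation: all retained skull voxels get
#'     one fixed bone LAC (`bone_mu`), and a seeded `flip_fraction` of
#'     skull-boundary voxels is misclassified in each direction
#'     (bone -> soft and adjacent soft -> bone).}
#'   \item{DLDIXON}{deep-learning pseudo-CT: the true map plus small seeded
#'     voxelwise noise inside the head (sigma = `noise_sigma_frac` of soft
#'     mu, truncated at 5 sigma), no systematic bone error.}
#'   \item{CTAC}{exact copy (the reference).}
#' }
#'
#' @param mu_ct ground-truth mu-map (`voxel_volume`, 1/mm).
#' @param atlas label atlas on the same grid; label 2 is the skull, 0 air.
#' @param spec an [mrac_variant()].
#' @param seed integer seed for the stochastic degradations (UTE, DLDIXON).
#' @param skull_label atlas id of the skull shell.
#' @return a `voxel_volume` of kind `mu` on the same grid.
#' @export
derive_mrac <- function(mu_ct, atlas, spec, seed = 1L, skull_label = 2L) {
  stopifnot(inherits(mu_ct, "voxel_volume"), inherits(atlas, "voxel_volume"))
  if (!inherits(spec, "mrac_variant")) spec <- mrac_variant(spec)
  stop_if_grid_mismatch(mu_ct, atlas, "mu_ct and atlas")
  p <- spec$parameters
  out <- mu_ct$data
  skull <- atlas$data == skull_label

  if (spec$name == "CTAC") {
    # identity
  } else if (spec$name == "DIXON") {
    out[skull] <- p$mu_soft
  } else if (spec$name == "DIXONBONE") {
    kept <- erode_mask(skull, iterations = p$erosion_voxels)
    out[skull & !kept] <- p$mu_soft
    out[kept] <- p$bone_scale * mu_ct$data[kept]
  } else if (spec$name == "UTE") {
    out[skull] <- p$bone_mu
    boundary_bone <- skull & dilate_mask(!skull)
    boundary_soft <- !skull & atlas$data > 0L & dilate_mask(skull)
    flips <- with_seed(seed, list(
      to_soft = sample(which(boundary_bone),
                       floor(p$flip_fraction * sum(boundary_bone))),
      to_bone = sample(which(boundary_soft),
                       floor(p$flip_fraction * sum(boundary_soft)))))
    out[flips$to_soft] <- p$mu_soft
    out[flips$to_bone] <- p$bone_mu
  } else if (spec$name == "DLDIXON") {
    head_mask <- atlas$data > 0L
    sigma <- p$noise_sigma_frac * p$mu_soft
    noise <- with_seed(seed, stats::rnorm(sum(head_mask), sd = sigma))
    noise <- pmin(pmax(noise, -5 * sigma), 5 * sigma)
    out[head_mask] <- pmax(out[head_mask] + noise, 0)
  }
  voxel_volume(out, mu_ct$spacing, mu_ct$origin, kind = "mu")
}

#' Rasterize a sphere onto a volume grid
#'
#' Voxel-centre inclusion: a mask voxel is 1 exactly when its centre's world
#' coordinate lies within `radius` of `center`. No partial-volume weighting
#' is applied at rasterization; downstream PSF smoothing supplies edge
#' softness.
#'
#' @param grid a `voxel_volume` whose grid (shape, spacing, origin) defines
#'   the mask raster.
#' @param center world coordinate (mm), length 3.
#' @param radius sphere radius in mm (> 0).
#' @return a binary `voxel_volume` (kind `label`); if the sphere lies wholly
#'   outside the grid the mask is empty and a warning is raised.
#' @export
rasterize_sphere <- function(grid, center, radius) {
  stopifnot(inherits(grid, "voxel_volume"), length(center) == 3)
  if (radius <= 0) stop("radius must be > 0")
  dx2 <- (voxel_centers(grid, 1) - center[1])^2
  dy2 <- (voxel_centers(grid, 2) - center[2])^2
  dz2 <- (voxel_centers(grid, 3) - center[3])^2
  d <- dim(grid$data)
  within <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= radius^2
  if (!any(within))
    warning("sphere lies entirely outside the grid; mask is empty")
  voxel_volume(array(as.integer(within), d), grid$spacing, grid$origin,
               kind = "label")
}

#' Write a phantom bundle to disk
#'
#' Volumes go out as NIfTI-1 (`activity.nii.gz`, `atlas.nii.gz`,
#' `mu_ct.nii.gz`), the label table as `labels.csv` (id, name, near_skull).
#'
#' @param bundle a `phantom_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(bundle, dir) {
  stopifnot(inherits(bundle, "phantom_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(bundle$activity, file.path(dir, "activity.nii.gz"))
  write_volume(bundle$atlas, file.path(dir, "atlas.nii.gz"))
  write_volume(bundle$mu_ct, file.path(dir, "mu_ct.nii.gz"))
  utils::write.csv(bundle$labels, file.path(dir, "labels.csv"),
                   row.names = FALSE)
  invisible(dir)
}
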