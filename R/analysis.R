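#' Mean image value over an atlas region
#'
#' @param image a `voxel_volume`.
#' @param atlas label atlas `voxel_volume` on the same grid (resample with
#'   [resample_nearest()] first otherwise).
#' @param label integer label id; must be present in the atlas.
#' @return arithmetic mean of `image` over the voxels carrying `label`.
#' @export
roi_mean <- function(image, atlas, label) {
  stopifnot(inherits(image, "voxel_volume"), inherits(atlas, "voxel_volume"))
  stop_if_grid_mismatch(image, atlas, "image and atlas")
  sel <- atlas$data == label
  if (!any(sel)) {
    present <- sort(unique(as.vector(atlas$data)))
    stop("label ", label, " absent from atlas; present labels: ",
         paste(present, collapse = ", "))
  }
  mean(image$data[sel])
}

#' MRAC-to-CTAC activity bias
#'
#' `bias = (mean_mrac - mean_ctac) / mean_ctac`, dimensionless; multiply by
#' 100 for the percent convention used in all CSV outputs.
#'
#' @param mean_mrac,mean_ctac regional activity means under the MR-based and
#'   the reference CT-based attenuation correction.
#' @return the fractional bias.
#' @export
bias <- function(mean_mrac, mean_ctac) {
  if (any(mean_ctac == 0)) stop("mean_ctac must be non-zero")
  (mean_mrac - mean_ctac) / mean_ctac
}

#' Cohort summaries of bias records
#'
#' Per group: median, first and third quartiles (linear-interpolation
#' quantile convention, type 7) and count. Groups with no record are
#' dropped.
#'
#' @param records data.frame of bias records (see [run_experiment()]) with a
#'   numeric `bias` column.
#' @param group_by character vector of grouping columns, e.g.
#'   `c("method", "arm")` or `c("method", "arm", "roi")`.
#' @return data.frame with the grouping columns plus `median_bias`, `q1`,
#'   `q3`, `n`.
#' @export
cohort_summary <- function(records, group_by = c("method", "arm")) {
  stopifnot(is.data.frame(records), "bias" %in% names(records),
            all(group_by %in% names(records)))
  if (nrow(records) == 0L) stop("at least one record per group is required")
  key <- interaction(records[group_by], drop = TRUE, lex.order = TRUE)
  out <- do.call(rbind, lapply(split(records, key), function(d) {
    q <- stats::quantile(d$bias, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    cbind(d[1, group_by, drop = FALSE],
          data.frame(median_bias = q[2], q1 = q[1], q3 = q[3], n = nrow(d)))
  }))
  rownames(out) <- NULL
  out
}

#' Run the three-arm attenuation-correction comparison on one phantom
#'
#' Mirrors the evaluation design: lesions are inserted into the projection
#' space and reconstructed (arm `with_background`: lesion counts added to the
#' phantom's emission sinogram; arm `lesion_only`: the lesion sinogram alone),
#' and the plain phantom is reconstructed as-is (arm `original`). Within each
#' arm the counts are simulated ONCE — with the ground-truth CT mu-map — and
#' every attenuation-map variant reconstructs those same counts, so only the
#' mu-map assumed by the reconstruction differs and the attenuation-induced
#' bias is isolated from noise. Regional means are taken over each lesion's
#' geometric support (lesion arms) or over every brain atlas region
#' (`original`), on the post-filtered reconstructions, and compared to the
#' CTAC reconstruction of the same counts via [bias()].
#'
#' @param bundle a [generate_phantom()] bundle.
#' @param lesions list of [lesion_spec()]s; defaults to the two 4 mm-radius
#'   spheres of [default_lesions()] (one near the skull, one interior).
#' @param variants character vector or list of [mrac_variant()]s; must
#'   include `CTAC` (the reference).
#' @param geometry [sino_geometry()]; slice count defaults to the phantom's.
#' @param params a [recon_params()].
#' @param scatter_fraction,duration_scale,norm_mode acquisition settings
#'   (see [acquisition_model()] and [make_normalization()]).
#' @param noiseless if `TRUE` the expected counts are reconstructed without
#'   a Poisson draw (useful for deterministic property checks).
#' @param arms subset of `c("with_background", "lesion_only", "original")`.
#' @param seed integer; seeds the Poisson realizations and the stochastic
#'   mu-map degradations.
#' @param phantom_id identifier copied into the records.
#' @return data.frame of bias records: `phantom_id`, `method`, `arm`, `roi`,
#'   `mean_mrac`, `mean_ctac`, `bias`, `bias_percent`.
#' @export
run_experiment <- function(bundle, lesions = default_lesions(bundle),
                           variants = c("CTAC", "DIXON", "DIXONBONE", "UTE",
                                        "DLDIXON"),
                           geometry = NULL, params = recon_params(),
                           scatter_fraction = 0.3, duration_scale = 1e-4,
                           norm_mode = "uniform", noiseless = FALSE,
                           arms = c("with_background", "lesion_only",
                                    "original"),
                           seed = 1L, phantom_id = bundle$seed) {
  stopifnot(inherits(bundle, "phantom_bundle"))
  arms <- match.arg(arms, several.ok = TRUE)
  variants <- lapply(variants, function(v)
    if (inherits(v, "mrac_variant")) v else mrac_variant(v))
  vnames <- vapply(variants, `[[`, "", "name")
  if (!"CTAC" %in% vnames)
    stop("'variants' must include CTAC, the reference")
  if (anyDuplicated(vnames)) stop("duplicate variant names")

  grid <- bundle$activity
  nz <- dim(grid$data)[3]
  if (is.null(geometry))
    geometry <- sino_geometry(n_slices = nz,
                              slice_spacing = grid$spacing[3])
  norm <- make_normalization(geometry, norm_mode,
                             seed = derive_seed(seed, 900))

  # mu-maps and per-variant reconstruction models (data are always generated
  # with the ground-truth CT map; only the reconstruction's map varies)
  mu_maps <- lapply(variants, function(v)
    derive_mrac(bundle$mu_ct, bundle$atlas, v,
                seed = derive_seed(bundle$seed, match(v$name, vnames))))
  names(mu_maps) <- vnames
  models <- lapply(mu_maps, function(m)
    acquisition_model(geometry, compute_acf(m, geometry), norm,
                      scatter_fraction = scatter_fraction,
                      duration_scale = duration_scale))
  model_true <- models[["CTAC"]]  # CTAC acf equals the ground-truth acf

  bg_comp <- expected_components(bundle$activity, model_true)
  lesion_vols <- lapply(lesions, lesion_activity_volume, atlas = bundle$atlas,
                        background_activity = bundle$activity)
  lesion_total <- Reduce(`+`, lapply(lesion_vols, `[[`, "data"))
  les_comp <- expected_components(
    voxel_volume(lesion_total, grid$spacing, grid$origin, kind = "activity"),
    model_true)
  lesion_masks <- lapply(lesions, lesion_mask, atlas = bundle$atlas)
  lesion_names <- names(lesions)
  if (is.null(lesion_names) || any(!nzchar(lesion_names)))
    lesion_names <- vapply(seq_along(lesions), function(i)
      lesion_roi_name(lesions[[i]], bundle), character(1))

  brain_ids <- bundle$labels$id[bundle$labels$id >= 3L]
  brain_names <- bundle$labels$name[bundle$labels$id >= 3L]

  realize <- function(expected, k) {
    sino <- sinogram(expected, geometry, "expected_counts")
    if (noiseless) sino else add_poisson(sino, derive_seed(seed, k))
  }

  records <- list()
  for (arm in arms) {
    arm_k <- match(arm, c("with_background", "lesion_only", "original"))
    if (arm == "with_background") {
      counts <- realize(bg_comp$trues + bg_comp$scatter +
                          les_comp$trues + les_comp$scatter, arm_k)
      scat <- bg_comp$scatter + les_comp$scatter
    } else if (arm == "lesion_only") {
      counts <- realize(les_comp$trues + les_comp$scatter, arm_k)
      scat <- les_comp$scatter
    } else {
      counts <- realize(bg_comp$trues + bg_comp$scatter, arm_k)
      scat <- bg_comp$scatter
    }
    scat_sino <- sinogram(scat, geometry, "scatter")
    recons <- lapply(models, function(m)
      osem(counts, m, scatter_estimate = scat_sino, params = params,
           grid = grid))
    if (arm == "original") {
      roi_ids <- brain_ids; roi_names_arm <- brain_names
      roi_mean_of <- function(img, i) roi_mean(img, bundle$atlas, roi_ids[i])
    } else {
      roi_names_arm <- lesion_names
      roi_mean_of <- function(img, i)
        mean(img$data[lesion_masks[[i]]$data == 1L])
    }
    ref <- recons[["CTAC"]]
    for (v in vnames) {
      for (i in seq_along(roi_names_arm)) {
        m_mrac <- roi_mean_of(recons[[v]], i)
        m_ctac <- roi_mean_of(ref, i)
        b <- bias(m_mrac, m_ctac)
        records[[length(records) + 1L]] <- data.frame(
          phantom_id = phantom_id, method = v, arm = arm,
          roi = roi_names_arm[i], mean_mrac = m_mrac, mean_ctac = m_ctac,
          bias = b, bias_percent = 100 * b, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  out
}

# Default evaluation lesions: 4 mm-radius spheres at a near-skull cortical
# position and an interior position, LBR 2, 4 mm PSF.
#' Default lesion pair for a phantom
#' @param bundle a `phantom_bundle`.
#' @param radius sphere radius in mm.
#' @param lbr lesion-to-background ratio.
#' @param psf_fwhm PSF FWHM in mm.
#' @return list of two [lesion_spec()]s named by position.
#' @export
default_lesions <- function(bundle, radius = 4, lbr = 2, psf_fwhm = 4) {
  zc <- 0  # phantom grids are centred on the world origin
  list(
    near_skull = lesion_spec("sphere", center = c(70, 14, zc),
                             radius = radius, lbr = lbr,
                             psf_fwhm = psf_fwhm),
    interior = lesion_spec("sphere", center = c(20, 14, zc),
                           radius = radius, lbr = lbr, psf_fwhm = psf_fwhm))
}

lesion_roi_name <- function(spec, bundle) {
  if (spec$shape == "atlas_roi") {
    nm <- bundle$labels$name[bundle$labels$id == spec$label]
    return(sprintf("lesion_roi_%s", nm))
  }
  sprintf("lesion_sphere_%g_%g_%g", spec$center[1], spec$center[2],
          spec$center[3])
}

#' Run the experiment over a seeded phantom cohort
#'
#' One phantom per seed (the synthetic analogue of a multi-patient cohort),
#' each pushed through [run_experiment()]; records are concatenated with the
#' seed as `phantom_id`.
#'
#' @param seeds integer vector of phantom seeds (default `1:11`).
#' @param ... passed to [generate_phantom()] (`grid`, `spacing`, `n_rois`,
#'   ...).
#' @param experiment_args list of arguments passed to [run_experiment()].
#' @return data.frame of bias records for the whole cohort.
#' @export
run_cohort <- function(seeds = 1:11, ..., experiment_args = list()) {
  do.call(rbind, lapply(seeds, function(s) {
    bundle <- generate_phantom(seed = s, ...)
    do.call(run_experiment,
            c(list(bundle = bundle, seed = s, phantom_id = s),
              experiment_args))
  }))
}

#' Box plots of cohort bias by method
#'
#' One panel per arm, one box per attenuation-map variant (CTAC omitted:
#' its bias is identically zero), bias in percent — the conventional way
#' these cohort comparisons are displayed.
#'
#' @param records data.frame from [run_experiment()] / [run_cohort()].
#' @param file output file (`.pdf` or `.png`), or `NULL` to draw on the
#'   current device.
#' @param roi optional ROI name to restrict to (default: all ROIs pooled).
#' @return `file` (or `NULL`), invisibly.
#' @export
plot_bias_boxplot <- function(records, file = NULL, roi = NULL) {
  stopifnot(is.data.frame(records))
  d <- records[records$method != "CTAC", ]
  if (!is.null(roi)) d <- d[d$roi == roi, ]
  if (nrow(d) == 0L) stop("no records to plot")
  arms <- unique(d$arm)
  if (!is.null(file)) {
    if (grepl("\\.png$", file)) grDevices::png(file, 480 * length(arms), 480)
    else grDevices::pdf(file, 4 * length(arms), 4)
    on.exit(grDevices::dev.off())
    graphics::par(mfrow = c(1, length(arms)))
  } else {
    op <- graphics::par(mfrow = c(1, length(arms)))
    on.exit(graphics::par(op))
  }
  for (a in arms) {
    da <- d[d$arm == a, ]
    graphics::boxplot(bias_percent ~ method, data = da,
                      ylab = "MRAC-to-CTAC bias (%)", xlab = "",
                      main = a, las = 2)
    graphics::abline(h = 0, lty = 3)
  }
  invisible(file)
}

#' Write bias records and cohort summaries to CSV
#'
#' Long-format records (`bias_percent` with two decimals, matching the
#' percent reporting convention) plus a per-(method, arm, roi) summary.
#'
#' @param records data.frame from [run_experiment()] / [run_cohort()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_bias_tables <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- records
  rec$bias_percent <- round(rec$bias_percent, 2)
  utils::write.csv(rec, file.path(dir, "bias_records.csv"),
                   row.names = FALSE)
  summ <- cohort_summary(records, c("method", "arm", "roi"))
  summ$median_percent <- round(100 * summ$median_bias, 2)
  summ$q1_percent <- round(100 * summ$q1, 2)
  summ$q3_percent <- round(100 * summ$q3, 2)
  utils::write.csv(summ[c("method", "arm", "roi", "median_percent",
                          "q1_percent", "q3_percent", "n")],
                   file.path(dir, "bias_summary.csv"), row.names = FALSE)
  invisible(dir)
}
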