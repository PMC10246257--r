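#' Lesion specifications
#'
#' Describes one synthetic lesion: its geometry (a sphere in world
#' coordinates or an existing atlas region) and its activity rule (an
#' absolute concentration or a lesion-to-background ratio, LBR, relative to
#' the mean background activity over the lesion support), plus the scanner
#' point-spread-function FWHM applied to the lesion volume before
#' projection.
#'
#' @param shape `"sphere"` or `"atlas_roi"`.
#' @param center,radius sphere centre (mm, world) and radius (mm, > 0).
#' @param label atlas label id for `atlas_roi`.
#' @param activity absolute activity (Bq/mL); exclusive with `lbr`.
#' @param lbr lesion-to-background ratio (> 0); requires a background
#'   activity image when the lesion volume is built.
#' @param psf_fwhm isotropic Gaussian PSF FWHM in mm (0 disables smoothing).
#' @return an object of class `lesion_spec`.
#' @export
lesion_spec <- function(shape = c("sphere", "atlas_roi"), center = NULL,
                        radius = NULL, label = NULL, activity = NULL,
                        lbr = NULL, psf_fwhm = 4) {
  shape <- match.arg(shape)
  if (shape == "sphere") {
    if (is.null(center) || is.null(radius) || radius <= 0)
      stop("sphere lesions need 'center' and a radius > 0")
  } else if (is.null(label)) {
    stop("atlas_roi lesions need a 'label' id")
  }
  if (is.null(activity) == is.null(lbr))
    stop("give exactly one of 'activity' (absolute) or 'lbr' (ratio)")
  if (!is.null(lbr) && lbr <= 0) stop("'lbr' must be > 0")
  structure(list(shape = shape, center = center, radius = radius,
                 label = label, activity = activity, lbr = lbr,
                 psf_fwhm = psf_fwhm),
            class = "lesion_spec")
}

#' @export
print.lesion_spec <- function(x, ...) {
  geom <- if (x$shape == "sphere")
    sprintf("sphere r=%g mm at (%s)", x$radius,
            paste(x$center, collapse = ", "))
  else sprintf("atlas ROI label %d", x$label)
  rule <- if (!is.null(x$activity)) sprintf("abs=%g", x$activity)
          else sprintf("lbr=%g", x$lbr)
  cat(sprintf("<lesion_spec> %s, %s, psf %g mm\n", geom, rule, x$psf_fwhm))
  invisible(x)
}

#' Lesion mask on a grid
#' @param spec a [lesion_spec()].
#' @param atlas label atlas `voxel_volume` defining the grid (and the region
#'   for `atlas_roi` lesions).
#' @return binary `voxel_volume` of the lesion's geometric support
#'   (un-smoothed; this is also the support ROI used for bias measurement).
#' @export
lesion_mask <- function(spec, atlas) {
  stopifnot(inherits(spec, "lesion_spec"), inherits(atlas, "voxel_volume"))
  if (spec$shape == "sphere") {
    rasterize_sphere(atlas, spec$center, spec$radius)
  } else {
    if (!any(atlas$data == spec$label))
      stop("atlas label ", spec$label, " not present in atlas")
    voxel_volume(array(as.integer(atlas$data == spec$label), dim(atlas$data)),
                 atlas$spacing, atlas$origin, kind = "label")
  }
}

#' Build the lesion activity volume
#'
#' Produces the activity image that will be forward projected: zero outside
#' the lesion support; inside, either the absolute activity or (LBR rule)
#' the mean of the background activity over the support times the ratio. The
#' result is then convolved with the isotropic Gaussian scanner PSF of
#' `psf_fwhm`.
#'
#' @param spec a [lesion_spec()].
#' @param atlas label atlas `voxel_volume` (defines the grid).
#' @param background_activity background activity `voxel_volume`; required
#'   for the LBR rule.
#' @return an activity `voxel_volume` on the atlas grid.
#' @export
lesion_activity_volume <- function(spec, atlas, background_activity = NULL) {
  mask <- lesion_mask(spec, atlas)
  n_in <- sum(mask$data)
  if (n_in == 0L) stop("lesion mask is empty on this grid")
  if (!is.null(spec$lbr)) {
    if (is.null(background_activity))
      stop("the LBR activity rule requires a background activity image")
    stop_if_grid_mismatch(atlas, background_activity,
                          "atlas and background activity")
    bg_mean <- mean(background_activity$data[mask$data == 1L])
    if (bg_mean <= 0)
      stop("background activity mean over the lesion is zero; ",
           "an LBR lesion is undefined there")
    value <- bg_mean * spec$lbr
  } else {
    value <- spec$activity
  }
  les <- value * mask$data
  if (spec$psf_fwhm > 0) {
    sigma_vox <- fwhm_to_sigma(spec$psf_fwhm) / atlas$spacing
    les <- gaussian_smooth_array(les, sigma_vox)
    les[les < 0] <- 0
  }
  voxel_volume(les, atlas$spacing, atlas$origin, kind = "activity")
}

#' Acquisition model
#'
#' Bundles everything that turns an activity image into expected sinogram
#' counts: the geometry, the attenuation correction factors of the mu-map the
#' data are generated (or modeled) with, the normalization, a global scatter
#' fraction, and a duration scale converting activity line integrals into
#' expected counts.
#'
#' @param geometry a [sino_geometry()].
#' @param acf `sinogram` of role `acf` (from [compute_acf()]).
#' @param norm `sinogram` of role `normalization`, or `NULL` for uniform.
#' @param scatter_fraction global scatter fraction in \[0, 1).
#' @param duration_scale scalar converting activity line integrals
#'   (Bq/mL * mm) to expected counts per bin. The default yields on the
#'   order of 2e6 total counts for the default phantom, a noise regime
#'   comparable to a 30-minute brain acquisition at this desk scale.
#' @param scatter_fwhm radial FWHM (mm) of the broad Gaussian scatter model.
#' @return an object of class `acquisition_model`.
#' @export
acquisition_model <- function(geometry, acf, norm = NULL,
                              scatter_fraction = 0.3,
                              duration_scale = 1e-4, scatter_fwhm = 80) {
  stopifnot(inherits(geometry, "sino_geometry"), inherits(acf, "sinogram"))
  if (acf$role != "acf") stop("'acf' must have role \"acf\"")
  if (is.null(norm)) norm <- make_normalization(geometry, "uniform")
  if (norm$role != "normalization")
    stop("'norm' must have role \"normalization\"")
  if (!same_geometry(acf$geometry, geometry) ||
      !same_geometry(norm$geometry, geometry))
    stop("acf and norm must share the model geometry")
  if (scatter_fraction < 0 || scatter_fraction >= 1)
    stop("scatter_fraction must lie in [0, 1)")
  structure(list(geometry = geometry, acf = acf, norm = norm,
                 scatter_fraction = scatter_fraction,
                 duration_scale = duration_scale,
                 scatter_fwhm = scatter_fwhm),
            class = "acquisition_model")
}

# Trues and scatter components of the expected-counts chain.
expected_components <- function(activity, model) {
  stopifnot(inherits(model, "acquisition_model"))
  if (any(activity$data < 0)) stop("activity must be non-negative")
  li <- forward_project(activity, model$geometry)
  trues <- model$duration_scale * model$norm$data * li$data / model$acf$data
  sf <- model$scatter_fraction
  if (sf > 0 && sum(trues) > 0) {
    sigma_bins <- fwhm_to_sigma(model$scatter_fwhm) /
      model$geometry$radial_spacing
    smoothed <- gaussian_smooth_array(aperm(trues, c(2, 1, 3)),
                                      c(sigma_bins, 0, 0))
    smoothed <- aperm(smoothed, c(2, 1, 3))
    # rescale so scatter / (trues + scatter) = scatter_fraction globally
    scatter <- smoothed * (sf / (1 - sf)) * sum(trues) / sum(smoothed)
  } else {
    scatter <- array(0, dim(trues))
  }
  list(trues = trues, scatter = scatter)
}

#' Expected-counts sinogram of an activity image
#'
#' The forward emission chain: forward projection, attenuation (division by
#' the ACF), normalization and duration scaling give the expected trues;
#' scatter is added as a globally-scaled broad radial Gaussian of the trues
#' so that `scatter / (trues + scatter)` equals the model's scatter fraction
#' exactly.
#'
#' @param activity an activity `voxel_volume`.
#' @param model an [acquisition_model()].
#' @return a `sinogram` with role `expected_counts`.
#' @export
expected_counts <- function(activity, model) {
  comp <- expected_components(activity, model)
  sinogram(comp$trues + comp$scatter, model$geometry, "expected_counts")
}

#' Poisson noise
#'
#' Draws each bin independently from a Poisson distribution with that bin's
#' expectation; reproducible under `seed`.
#'
#' @param expected a `sinogram` of role `expected_counts` (or `scatter` /
#'   `line_integrals` scaled to counts).
#' @param seed integer seed.
#' @return a `sinogram` with role `counts`.
#' @export
add_poisson <- function(expected, seed = 1L) {
  stopifnot(inherits(expected, "sinogram"))
  if (any(expected$data < 0)) stop("expected counts must be non-negative")
  counts <- with_seed(seed,
                      stats::rpois(length(expected$data),
                                   as.vector(expected$data)))
  sinogram(array(as.numeric(counts), dim(expected$data)),
           expected$geometry, "counts")
}

#' Projection-space support of a lesion sinogram
#' @param lesion_expected a `sinogram` of expected lesion counts.
#' @param threshold_frac bins above `threshold_frac * max` form the support.
#' @return a binary array shaped like the sinogram data.
#' @export
lesion_support_mask <- function(lesion_expected, threshold_frac = 1e-12) {
  stopifnot(inherits(lesion_expected, "sinogram"))
  m <- max(lesion_expected$data)
  lesion_expected$data > threshold_frac * m
}

#' Compose a lesion sinogram with a background sinogram
#'
#' The lesion insertion step: a Poisson realization of the expected lesion
#' counts is either added to the background counts (`add`), overwrites the
#' background on the lesion's projection support only (`replace`), or stands
#' alone (`lesion_only`, the no-emission-data arm).
#'
#' @param background `sinogram` of role `counts`, or `NULL` (only for
#'   `lesion_only`).
#' @param lesion_expected `sinogram` of role `expected_counts`.
#' @param mode `"add"`, `"replace"` or `"lesion_only"`.
#' @param support binary array from [lesion_support_mask()]; computed from
#'   `lesion_expected` when `NULL`.
#' @param seed integer seed for the lesion's Poisson draw.
#' @return a `sinogram` with role `counts`.
#' @export
compose <- function(background, lesion_expected,
                    mode = c("add", "replace", "lesion_only"),
                    support = NULL, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(lesion_expected, "sinogram"))
  if (mode != "lesion_only") {
    if (is.null(background))
      stop("mode '", mode, "' requires a background counts sinogram")
    stopifnot(inherits(background, "sinogram"))
    if (!same_geometry(background$geometry, lesion_expected$geometry))
      stop("background and lesion sinograms must share one geometry")
  }
  lesion_counts <- add_poisson(lesion_expected, seed)
  out <- switch(mode,
    lesion_only = lesion_counts$data,
    add = background$data + lesion_counts$data,
    replace = {
      if (is.null(support)) support <- lesion_support_mask(lesion_expected)
      d <- background$data
      d[support] <- lesion_counts$data[support]
      d
    })
  sinogram(out, lesion_expected$geometry, "counts")
}
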