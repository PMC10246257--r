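#' Reconstruction parameters
#'
#' Defaults follow common clinical brain protocol settings: 3 iterations,
#' 24 subsets, 4 mm Gaussian post-filter.
#'
#' @param n_iterations full OSEM iterations (each cycles all subsets).
#' @param n_subsets number of angle-interleaved subsets; must divide the
#'   geometry's angle count.
#' @param post_filter_fwhm isotropic Gaussian post-filter FWHM in mm (0
#'   disables).
#' @param initial_value uniform starting image value inside the field of
#'   view (> 0).
#' @param nonneg_floor small positive floor protecting the multiplicative
#'   update against division by zero.
#' @return an object of class `recon_params`.
#' @export
recon_params <- function(n_iterations = 3L, n_subsets = 24L,
                         post_filter_fwhm = 4, initial_value = 1,
                         nonneg_floor = 1e-12) {
  stopifnot(n_iterations >= 1, n_subsets >= 1, post_filter_fwhm >= 0,
            initial_value > 0, nonneg_floor > 0)
  structure(list(n_iterations = as.integer(n_iterations),
                 n_subsets = as.integer(n_subsets),
                 post_filter_fwhm = post_filter_fwhm,
                 initial_value = initial_value,
                 nonneg_floor = nonneg_floor),
            class = "recon_params")
}

# Angle-interleaved subsets: subset k takes angles k, k + n_subsets, ...
subset_angle_indices <- function(n_angles, n_subsets) {
  if (n_angles %% n_subsets != 0)
    stop("n_angles (", n_angles, ") must be divisible by n_subsets (",
         n_subsets, ")")
  lapply(seq_len(n_subsets), function(k)
    seq.int(k, n_angles, by = n_subsets))
}

#' Ordered-subsets expectation maximization (OSEM)
#'
#' Classic multiplicative OSEM with attenuation, normalization and an
#' additive scatter term in the forward model (ordinary-Poisson form, no
#' pre-subtraction). Per subset `s`:
#' `x <- x * backproj_s(p_s * y_s / (p_s * fwd_s(x) + scat_s)) /
#'  backproj_s(p_s)` with `p = duration_scale * norm / acf`. Voxels with
#' zero sensitivity (outside the field of view) are set to zero, never NaN.
#' With `n_subsets = 1` this is MLEM and the Poisson log-likelihood is
#' non-decreasing across iterations. A Gaussian post-filter of
#' `post_filter_fwhm` is applied at the end.
#'
#' @param counts measured (or noiseless expected) `sinogram`.
#' @param model an [acquisition_model()]; its `acf` is the attenuation map
#'   assumed by the reconstruction, which need not be the one the data were
#'   generated with (that mismatch is the object of study).
#' @param scatter_estimate `sinogram` of the scatter expectation used in the
#'   forward model, or `NULL` for none.
#' @param params a [recon_params()].
#' @param grid `voxel_volume` defining the target image grid.
#' @return the reconstructed activity `voxel_volume`.
#' @export
osem <- function(counts, model, scatter_estimate = NULL,
                 params = recon_params(), grid) {
  stopifnot(inherits(counts, "sinogram"), inherits(model, "acquisition_model"),
            inherits(params, "recon_params"), inherits(grid, "voxel_volume"))
  g <- model$geometry
  if (!same_geometry(counts$geometry, g))
    stop("counts sinogram geometry does not match the model")
  scat <- if (is.null(scatter_estimate)) array(0, dim(counts$data)) else {
    if (!same_geometry(scatter_estimate$geometry, g))
      stop("scatter estimate geometry does not match the model")
    scatter_estimate$data
  }
  subsets <- subset_angle_indices(g$n_angles, params$n_subsets)
  angles <- sino_angles(g)
  p <- model$duration_scale * model$norm$data / model$acf$data
  dims <- dim(grid$data)
  floorv <- params$nonneg_floor

  fwd_sub <- function(x, idx)
    array(joseph_forward_cpp(as.vector(x), dims, grid$spacing, grid$origin,
                             angles[idx], g$n_radial, g$radial_spacing),
          c(length(idx), g$n_radial, g$n_slices))
  back_sub <- function(y, idx)
    array(joseph_backward_cpp(as.vector(y), dims, grid$spacing, grid$origin,
                              angles[idx], g$n_radial, g$radial_spacing),
          dims)

  # Per-subset sensitivity images; their union defines the in-FOV mask.
  sens <- lapply(subsets, function(idx)
    back_sub(p[idx, , , drop = FALSE], idx))
  fov <- Reduce(`+`, sens) > 0

  x <- array(params$initial_value, dims)
  x[!fov] <- 0
  for (it in seq_len(params$n_iterations)) {
    for (k in seq_along(subsets)) {
      idx <- subsets[[k]]
      ybar <- p[idx, , , drop = FALSE] * fwd_sub(x, idx) +
        scat[idx, , , drop = FALSE]
      ratio <- counts$data[idx, , , drop = FALSE] / pmax(ybar, floorv)
      upd <- back_sub(p[idx, , , drop = FALSE] * ratio, idx)
      sk <- sens[[k]]
      pos <- sk > 0
      x[pos] <- x[pos] * upd[pos] / sk[pos]
    }
  }
  x[x < 0] <- 0
  out <- voxel_volume(x, grid$spacing, grid$origin, kind = "activity")
  if (params$post_filter_fwhm > 0)
    out <- gaussian_post_filter(out, params$post_filter_fwhm)
  out
}

#' Gaussian post-reconstruction filter
#'
#' Separable isotropic Gaussian with `sigma = fwhm / 2.3548` per axis in mm
#' (converted to voxels by the spacing); reflective boundaries, so constants
#' pass through unchanged. `fwhm = 0` is the identity.
#'
#' @param volume a `voxel_volume`.
#' @param fwhm full width at half maximum in mm (>= 0).
#' @return the filtered `voxel_volume`.
#' @export
gaussian_post_filter <- function(volume, fwhm) {
  stopifnot(inherits(volume, "voxel_volume"), fwhm >= 0)
  if (fwhm == 0) return(volume)
  sigma_vox <- fwhm_to_sigma(fwhm) / volume$spacing
  out <- gaussian_smooth_array(volume$data, sigma_vox)
  if (volume$kind == "activity") out[out < 0] <- 0
  voxel_volume(out, volume$spacing, volume$origin, kind = volume$kind)
}

#' Poisson log-likelihood of counts under an expected-counts model
#'
#' `sum(y * log(ybar) - ybar)` over all bins (the data-dependent constant
#' `-log(y!)` is omitted), with the convention `0 * log(0) = 0`. Used to
#' verify the monotone-likelihood property of MLEM.
#'
#' @param counts `sinogram` of observed counts.
#' @param expected `sinogram` of model expectations (same geometry).
#' @return a scalar log-likelihood (up to a constant).
#' @export
poisson_loglik <- function(counts, expected) {
  stopifnot(inherits(counts, "sinogram"), inherits(expected, "sinogram"))
  y <- as.vector(counts$data)
  m <- as.vector(expected$data)
  ll <- -sum(m)
  pos <- y > 0
  if (any(pos & m <= 0)) return(-Inf)
  ll + sum(y[pos] * log(m[pos]))
}

#' Expected-counts sinogram of a reconstruction under a model
#'
#' Convenience for likelihood tracking: applies the model forward chain to
#' an image and adds the supplied scatter expectation.
#'
#' @param image `voxel_volume`.
#' @param model an [acquisition_model()].
#' @param scatter_estimate `sinogram` or `NULL`.
#' @return a `sinogram` with role `expected_counts`.
#' @export
model_forward <- function(image, model, scatter_estimate = NULL) {
  li <- forward_project(image, model$geometry)
  d <- model$duration_scale * model$norm$data * li$data / model$acf$data
  if (!is.null(scatter_estimate)) d <- d + scatter_estimate$data
  sinogram(d, model$geometry, "expected_counts")
}
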