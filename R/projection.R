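#' Forward projection (line integrals)
#'
#' Projects a volume into sinogram space under the package's multi-slice 2-D
#' parallel-beam model: each bin holds the line integral (value * mm) of the
#' volume along a transaxial ray, computed per slice with Joseph-style
#' bilinear sampling. The operator is linear and is the exact matrix
#' transpose of [back_project()].
#'
#' @param volume a `voxel_volume`; its slices must match the geometry
#'   (`nz == n_slices`, axial spacing equal to `slice_spacing`). The axis of
#'   rotation is the world origin.
#' @param geometry a [sino_geometry()] whose transaxial field of view covers
#'   the support (non-zero voxels) of the volume.
#' @return a `sinogram` with role `line_integrals`.
#' @export
forward_project <- function(volume, geometry) {
  check_projection_compat(volume, geometry)
  out <- joseph_forward_cpp(as.vector(volume$data), dim(volume$data),
                            volume$spacing, volume$origin,
                            sino_angles(geometry), geometry$n_radial,
                            geometry$radial_spacing)
  sinogram(array(out, c(geometry$n_angles, geometry$n_radial,
                        geometry$n_slices)),
           geometry, "line_integrals")
}

#' Backprojection (adjoint of the forward projector)
#'
#' Implements the exact adjoint of [forward_project()]: for any volume `x`
#' and sinogram `y` on matched grids,
#' `sum(forward_project(x) * y) == sum(x * back_project(y))` up to
#' floating-point rounding. This adjointness is the load-bearing numeric
#' contract behind the OSEM update.
#'
#' @param sino a `sinogram`.
#' @param grid a `voxel_volume` (only its grid is used) defining the target
#'   shape, spacing and origin.
#' @return a `voxel_volume` on the target grid.
#' @export
back_project <- function(sino, grid) {
  stopifnot(inherits(sino, "sinogram"), inherits(grid, "voxel_volume"))
  g <- sino$geometry
  if (dim(grid$data)[3] != g$n_slices)
    stop("sinogram has ", g$n_slices, " slices but target grid has ",
         dim(grid$data)[3])
  if (abs(grid$spacing[3] - g$slice_spacing) > 1e-6)
    stop("axial spacing of target grid does not match the sinogram geometry")
  out <- joseph_backward_cpp(as.vector(sino$data), dim(grid$data),
                             grid$spacing, grid$origin,
                             sino_angles(g), g$n_radial, g$radial_spacing)
  voxel_volume(array(out, dim(grid$data)), grid$spacing, grid$origin)
}

check_projection_compat <- function(volume, geometry) {
  stopifnot(inherits(volume, "voxel_volume"),
            inherits(geometry, "sino_geometry"))
  d <- dim(volume$data)
  if (d[3] != geometry$n_slices)
    stop("volume has ", d[3], " slices but geometry expects ",
         geometry$n_slices, "; resample first")
  if (abs(volume$spacing[3] - geometry$slice_spacing) > 1e-6)
    stop("volume axial spacing incompatible with geometry slice spacing; ",
         "resample first")
  r_support <- support_radius(volume)
  if (r_support > sino_fov_radius(geometry))
    stop(sprintf(paste0("geometry field of view (radius %.1f mm) is smaller ",
                        "than the volume support (radius %.1f mm)"),
                 sino_fov_radius(geometry), r_support))
  invisible(TRUE)
}

# Largest distance of any non-zero voxel centre from the rotation axis.
support_radius <- function(volume) {
  nz <- which(volume$data != 0, arr.ind = TRUE)
  if (nrow(nz) == 0L) return(0)
  x <- volume$origin[1] + (nz[, 1] - 1) * volume$spacing[1]
  y <- volume$origin[2] + (nz[, 2] - 1) * volume$spacing[2]
  sqrt(max(x * x + y * y))
}

#' Attenuation correction factors
#'
#' For each ray the attenuation correction factor (ACF) is
#' `exp(integral of mu along the ray)` with mu in 1/mm, so every bin is
#' >= 1. Applying attenuation to a trues sinogram means dividing it by the
#' ACF; correcting measured data means multiplying.
#'
#' @param mu_map a `voxel_volume` of kind `mu` (or non-negative values in
#'   1/mm) on a grid the geometry covers.
#' @param geometry a [sino_geometry()].
#' @return a `sinogram` with role `acf`.
#' @export
compute_acf <- function(mu_map, geometry) {
  stopifnot(inherits(mu_map, "voxel_volume"))
  if (any(mu_map$data < 0))
    stop("mu-map must be non-negative to form attenuation correction factors")
  li <- forward_project(mu_map, geometry)
  sinogram(exp(li$data), geometry, "acf")
}

#' Normalization sinograms
#'
#' Detector normalization modeled as a multiplicative per-bin efficiency.
#' `uniform` is all ones; `seeded_efficiency` draws each bin's efficiency
#' uniformly from \[0.9, 1.1\], reproducibly for a given geometry and seed.
#'
#' @param geometry a [sino_geometry()].
#' @param mode `"uniform"` or `"seeded_efficiency"`.
#' @param seed integer seed (used by `seeded_efficiency`).
#' @return a `sinogram` with role `normalization`.
#' @export
make_normalization <- function(geometry, mode = c("uniform",
                                                  "seeded_efficiency"),
                               seed = 1L) {
  mode <- match.arg(mode)
  d <- c(geometry$n_angles, geometry$n_radial, geometry$n_slices)
  data <- if (mode == "uniform") {
    array(1, d)
  } else {
    with_seed(seed, array(stats::runif(prod(d), 0.9, 1.1), d))
  }
  sinogram(data, geometry, "normalization")
}
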