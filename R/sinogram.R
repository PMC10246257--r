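#' Projection-space geometry
#'
#' The package models the scanner as a stack of independent 2-D parallel-beam
#' slices: each sinogram slice is indexed by projection angle (uniform over
#' \[0, pi)) and signed radial offset from the axis of rotation (the world
#' origin). This deliberately replaces the vendor's fully 3-D span/mashing
#' sinogram: the insertion and bias-measurement method is geometry-agnostic,
#' and the projector pair is pluggable behind [forward_project()] /
#' [back_project()].
#'
#' @param n_radial number of radial bins.
#' @param radial_spacing radial bin size in mm.
#' @param n_angles number of projection angles over \[0, pi).
#' @param n_slices number of axial slices.
#' @param slice_spacing axial slice thickness in mm.
#' @return an object of class `sino_geometry`.
#' @export
sino_geometry <- function(n_radial = 192, radial_spacing = 2,
                          n_angles = 96, n_slices = 1, slice_spacing = 2) {
  stopifnot(n_radial >= 2, n_angles >= 1, n_slices >= 1,
            radial_spacing > 0, slice_spacing > 0)
  g <- structure(list(n_radial = as.integer(n_radial),
                      radial_spacing = as.numeric(radial_spacing),
                      n_angles = as.integer(n_angles),
                      n_slices = as.integer(n_slices),
                      slice_spacing = as.numeric(slice_spacing)),
                 class = "sino_geometry")
  g
}

#' @export
print.sino_geometry <- function(x, ...) {
  cat(sprintf(
    "<sino_geometry> %d angles x %d radial (%.3g mm) x %d slices (%.3g mm)\n",
    x$n_angles, x$n_radial, x$radial_spacing, x$n_slices, x$slice_spacing))
  invisible(x)
}

#' Projection angles of a geometry
#' @param geometry a `sino_geometry`.
#' @return strictly increasing angles in radians, uniform over \[0, pi).
#' @export
sino_angles <- function(geometry) {
  (seq_len(geometry$n_angles) - 1) * pi / geometry$n_angles
}

#' Signed radial bin centres of a geometry, in mm (centred on zero offset)
#' @param geometry a `sino_geometry`.
#' @export
sino_radial_offsets <- function(geometry) {
  (seq_len(geometry$n_radial) - 1 - (geometry$n_radial - 1) / 2) *
    geometry$radial_spacing
}

#' Transaxial field-of-view radius of a geometry (mm)
#' @param geometry a `sino_geometry`.
#' @export
sino_fov_radius <- function(geometry) {
  geometry$n_radial * geometry$radial_spacing / 2
}

same_geometry <- function(a, b) {
  a$n_radial == b$n_radial && a$n_angles == b$n_angles &&
    a$n_slices == b$n_slices &&
    abs(a$radial_spacing - b$radial_spacing) < 1e-9 &&
    abs(a$slice_spacing - b$slice_spacing) < 1e-9
}

SINOGRAM_ROLES <- c("line_integrals", "acf", "normalization", "scatter",
                    "expected_counts", "counts")

#' Sinograms
#'
#' Projection-space data tied to a [sino_geometry()]. The `role` records what
#' the bins mean and activates role-specific invariants: `counts` must be
#' non-negative integers, `acf` (attenuation correction factors) must be
#' >= 1, `normalization` must be strictly positive.
#'
#' @param data numeric 3-D array `(n_angles, n_radial, n_slices)`.
#' @param geometry a `sino_geometry`.
#' @param role one of `"line_integrals"`, `"acf"`, `"normalization"`,
#'   `"scatter"`, `"expected_counts"`, `"counts"`.
#' @return an object of class `sinogram`.
#' @export
sinogram <- function(data, geometry, role) {
  role <- match.arg(role, SINOGRAM_ROLES)
  stopifnot(inherits(geometry, "sino_geometry"))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("sinogram 'data' must be a 3-D array (n_angles, n_radial, n_slices)")
  d <- dim(data)
  if (d[1] != geometry$n_angles || d[2] != geometry$n_radial ||
      d[3] != geometry$n_slices)
    stop("sinogram data dimensions do not match the geometry")
  if (role == "counts") {
    if (any(data < 0) || any(abs(data - round(data)) > 1e-9))
      stop("counts sinogram must hold non-negative integers")
    data <- round(data)
  }
  if (role == "acf" && any(data < 1 - 1e-9))
    stop("acf sinogram must be >= 1 everywhere (attenuation only removes counts)")
  if (role == "normalization" && any(data <= 0))
    stop("normalization sinogram must be strictly positive")
  structure(list(data = data, geometry = geometry, role = role),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<sinogram[%s]> %d angles x %d radial x %d slices, total %.4g\n",
              x$role, d[1], d[2], d[3], sum(x$data)))
  invisible(x)
}

#' Read and write sinograms
#'
#' A sinogram travels as a single-file container (serialized R object holding
#' the data array plus geometry metadata and role tag). For 2-D debugging a
#' single slice can be exported to CSV, one row per angle.
#'
#' @param sino a `sinogram`.
#' @param path file path (conventionally `.sino`).
#' @param slice 1-based slice index for the CSV export.
#' @return `read_sinogram` returns a `sinogram`; the writers return `path`
#'   invisibly.
#' @export
write_sinogram <- function(sino, path) {
  stopifnot(inherits(sino, "sinogram"))
  saveRDS(list(format = "petacval-sinogram-v1",
               data = sino$data,
               geometry = unclass(sino$geometry),
               role = sino$role),
          path)
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "petacval-sinogram-v1"))
    stop("not a petacval sinogram container: ", path)
  g <- do.call(sino_geometry, obj$geometry[c("n_radial", "radial_spacing",
                                             "n_angles", "n_slices",
                                             "slice_spacing")])
  sinogram(obj$data, g, obj$role)
}

#' @rdname write_sinogram
#' @export
export_sinogram_csv <- function(sino, path, slice = 1L) {
  stopifnot(inherits(sino, "sinogram"),
            slice >= 1L, slice <= sino$geometry$n_slices)
  m <- sino$data[, , slice]
  df <- data.frame(angle_rad = rep(sino_angles(sino$geometry),
                                   times = sino$geometry$n_radial),
                   radial_mm = rep(sino_radial_offsets(sino$geometry),
                                   each = sino$geometry$n_angles),
                   value = as.vector(m))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
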