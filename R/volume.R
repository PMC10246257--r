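#' Voxel volumes
#'
#' A `voxel_volume` is the package's container for every 3-D image: activity
#' (Bq/mL), attenuation maps (linear attenuation coefficient, 1/mm), CT-like
#' images (Hounsfield units) and integer label atlases. It couples a numeric
#' 3-D array with its voxel spacing and the world coordinate of the centre of
#' voxel (1,1,1) (right-handed axes, millimetres).
#'
#' @param data numeric 3-D array (nx, ny, nz).
#' @param spacing numeric length-3, voxel size in mm; strictly positive.
#' @param origin numeric length-3, world coordinate (mm) of the centre of the
#'   first voxel. Defaults to centring the volume on the world origin, which
#'   is also the projector's axis of rotation.
#' @param kind one of `"generic"`, `"activity"`, `"mu"`, `"hu"`, `"label"`.
#'   Role-specific invariants are enforced: activity is non-negative; a mu-map
#'   is within [0, 0.05] /mm (a sanity ceiling above cortical bone); a label
#'   atlas holds non-negative integers with 0 reserved for background/air.
#' @return an object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, spacing, origin = NULL,
                         kind = c("generic", "activity", "mu", "hu", "label")) {
  kind <- match.arg(kind)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3-D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three strictly positive values (mm)")
  if (is.null(origin))
    origin <- -(dim(data) - 1) / 2 * spacing
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be three finite values (mm)")
  storage.mode(data) <- if (kind == "label") "integer" else "double"
  vol <- structure(list(data = data, spacing = spacing, origin = origin,
                        kind = kind),
                   class = "voxel_volume")
  validate_voxel_volume(vol)
  vol
}

validate_voxel_volume <- function(vol) {
  x <- vol$data
  if (vol$kind == "activity" && any(x < 0))
    stop("activity volume must be non-negative")
  if (vol$kind == "mu") {
    if (any(x < 0)) stop("mu-map must be non-negative")
    if (any(x > 0.05))
      stop("mu-map exceeds 0.05 /mm, above any plausible 511 keV tissue LAC")
  }
  if (vol$kind == "label" && any(x < 0L))
    stop("label atlas must contain non-negative integers")
  invisible(vol)
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_volume[%s]> %d x %d x %d @ %.3g x %.3g x %.3g mm\n",
              x$kind, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (mm): %.2f, %.2f, %.2f   range: [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$data)

#' World coordinates of voxel centres along one axis
#' @param vol a `voxel_volume`.
#' @param axis 1, 2 or 3.
#' @return numeric vector of voxel-centre coordinates in mm.
#' @export
voxel_centers <- function(vol, axis) {
  n <- dim(vol$data)[axis]
  vol$origin[axis] + (seq_len(n) - 1) * vol$spacing[axis]
}

#' Voxel volume in cubic millimetres
#' @param vol a `voxel_volume`.
#' @export
voxel_volume_mm3 <- function(vol) prod(vol$spacing)

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(sprintf("%s must share an identical grid (shape, spacing, origin)",
                 what))
  invisible(TRUE)
}

#' Read and write voxel volumes as NIfTI-1
#'
#' Volumes are stored as `.nii` / `.nii.gz` with spacing and origin carried in
#' the header affine (sform, diagonal orientation). External inputs are
#' assumed already aligned to the grid they are used with: this package
#' performs no registration.
#'
#' @param vol a `voxel_volume`.
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @param kind role given to the volume on read (see [voxel_volume()]).
#' @return `read_volume` returns a `voxel_volume`; `write_volume` returns
#'   `path` invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "voxel_volume"))
  affine <- diag(c(vol$spacing, 1))
  affine[1:3, 4] <- vol$origin
  img <- RNifti::asNifti(vol$data)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, kind = "generic") {
  img <- RNifti::readNifti(path)
  affine <- RNifti::xform(img)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  if (kind == "label") arr <- array(as.integer(round(arr)), dim(arr))
  voxel_volume(arr,
               spacing = abs(c(affine[1, 1], affine[2, 2], affine[3, 3])),
               origin = affine[1:3, 4],
               kind = kind)
}
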