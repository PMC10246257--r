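#' Piecewise-linear HU-to-LAC conversion curves
#'
#' CT (and pseudo-CT) Hounsfield units are mapped to 511 keV linear
#' attenuation coefficients by piecewise-linear scaling between breakpoints,
#' clamping to the end segments outside their range. The default bilinear
#' curve runs (-1000 HU, 0 /mm) -> (0 HU, 0.0096 /mm) -> (1000 HU,
#' 0.0151 /mm): air to water with the soft-tissue slope, water to bone with
#' the reduced bone slope.
#'
#' @param breakpoints data.frame or 2-column matrix of `(hu, lac)` pairs; HU
#'   strictly increasing, LAC non-decreasing, passing through
#'   (0 HU, soft-tissue LAC) within 1e-4 /mm.
#' @return an object of class `hu_lac_curve`.
#' @export
hu_lac_curve <- function(breakpoints = default_hu_lac_breakpoints()) {
  bp <- as.data.frame(breakpoints)
  names(bp) <- c("hu", "lac")
  if (nrow(bp) < 2L) stop("need at least two breakpoints")
  if (any(diff(bp$hu) <= 0)) stop("HU breakpoints must be strictly increasing")
  if (any(diff(bp$lac) < 0)) stop("LAC values must be non-decreasing")
  if (any(bp$lac < 0)) stop("LAC values must be non-negative")
  at_water <- stats::approx(bp$hu, bp$lac, xout = 0, rule = 2)$y
  if (abs(at_water - tissue_mu_defaults()[["soft"]]) > 1e-4)
    stop("curve must pass through (0 HU, soft-tissue LAC) within 1e-4 /mm")
  structure(list(breakpoints = bp), class = "hu_lac_curve")
}

#' @rdname hu_lac_curve
#' @export
default_hu_lac_breakpoints <- function() {
  data.frame(hu = c(-1000, 0, 1000),
             lac = c(0, tissue_mu_defaults()[["soft"]],
                     tissue_mu_defaults()[["bone"]]))
}

#' Convert a Hounsfield-unit image to a 511 keV mu-map
#'
#' Per-voxel piecewise-linear interpolation on the curve, clamped to the end
#' segments outside the breakpoint range and floored at zero. Monotone: a
#' voxel with higher HU never maps to lower LAC.
#'
#' @param hu_image `voxel_volume` in Hounsfield units.
#' @param curve an [hu_lac_curve()].
#' @return a mu-map `voxel_volume` (1/mm).
#' @export
hu_to_lac <- function(hu_image, curve = hu_lac_curve()) {
  stopifnot(inherits(hu_image, "voxel_volume"),
            inherits(curve, "hu_lac_curve"))
  bp <- curve$breakpoints
  lac <- stats::approx(bp$hu, bp$lac, xout = as.vector(hu_image$data),
                       rule = 2)$y
  lac <- pmax(lac, 0)
  voxel_volume(array(lac, dim(hu_image$data)), hu_image$spacing,
               hu_image$origin, kind = "mu")
}

#' Nearest-neighbour resampling onto a target grid
#'
#' Each target voxel takes the value of the source voxel whose centre is
#' nearest in world coordinates; target voxels whose nearest source centre
#' falls outside the source grid take 0. Ties (exactly equidistant centres)
#' resolve to the lower source index, deterministically. Because values are
#' copied, never blended, label images keep exact integer labels and the
#' output value set is a subset of the source values plus 0.
#'
#' @param volume source `voxel_volume`.
#' @param shape,spacing,origin target grid definition (see
#'   [voxel_volume()]).
#' @return a `voxel_volume` of the source's kind on the target grid.
#' @export
resample_nearest <- function(volume, shape, spacing, origin = NULL) {
  stopifnot(inherits(volume, "voxel_volume"))
  shape <- as.integer(shape)
  if (is.null(origin)) origin <- -(shape - 1) / 2 * spacing
  idx <- vector("list", 3)
  any_overlap <- TRUE
  for (axis in 1:3) {
    tc <- origin[axis] + (seq_len(shape[axis]) - 1) * spacing[axis]
    u <- (tc - volume$origin[axis]) / volume$spacing[axis]  # 0-based source
    i <- ceiling(u - 0.5) + 1                       # ties -> lower index
    i[i < 1L | i > dim(volume$data)[axis]] <- NA_integer_
    if (all(is.na(i))) any_overlap <- FALSE
    idx[[axis]] <- i
  }
  if (!any_overlap)
    stop("source and target grids are disjoint along at least one axis")
  out <- array(0, shape)
  ok1 <- !is.na(idx[[1]]); ok2 <- !is.na(idx[[2]]); ok3 <- !is.na(idx[[3]])
  out[ok1, ok2, ok3] <- volume$data[idx[[1]][ok1], idx[[2]][ok2],
                                    idx[[3]][ok3]]
  voxel_volume(out, spacing, origin, kind = volume$kind)
}
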