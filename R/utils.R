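# RNG hygiene: every stochastic operation takes an explicit seed and leaves
# the caller's RNG stream untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic sub-seed derivation, kept inside 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %% 2147483647)
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Dense 1-D Gaussian convolution operator with reflective boundary; rows sum
# to one so constants pass through unchanged.
gauss_kernel_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  h <- max(1L, as.integer(ceiling(3 * sigma_vox)))
  k <- stats::dnorm(seq.int(-h, h), sd = sigma_vox)
  k <- k / sum(k)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- i + seq.int(-h, h)
    idx <- ifelse(idx < 1L, 2L - idx, idx)
    idx <- ifelse(idx > n, 2L * n - idx, idx)
    idx <- pmin(pmax(idx, 1L), n)
    for (m in seq_along(idx)) K[i, idx[m]] <- K[i, idx[m]] + k[m]
  }
  K
}

# Separable Gaussian smoothing of a 3-D array; sigma_vox is per-axis, in
# voxels. Reflective boundaries preserve constants and (away from edges) mass.
gaussian_smooth_array <- function(arr, sigma_vox) {
  d <- dim(arr)
  stopifnot(length(d) == 3L, length(sigma_vox) == 3L)
  if (sigma_vox[1] > 0) {
    K <- gauss_kernel_matrix(d[1], sigma_vox[1])
    arr <- array(K %*% matrix(arr, d[1]), d)
  }
  if (sigma_vox[2] > 0) {
    K <- gauss_kernel_matrix(d[2], sigma_vox[2])
    a <- aperm(arr, c(2, 1, 3))
    a <- array(K %*% matrix(a, d[2]), c(d[2], d[1], d[3]))
    arr <- aperm(a, c(2, 1, 3))
  }
  if (sigma_vox[3] > 0) {
    K <- gauss_kernel_matrix(d[3], sigma_vox[3])
    a <- aperm(arr, c(3, 1, 2))
    a <- array(K %*% matrix(a, d[3]), c(d[3], d[1], d[2]))
    arr <- aperm(a, c(2, 3, 1))
  }
  arr
}

# Binary 6-neighbourhood erosion/dilation with replicate padding, so a
# structure touching the array face is not eroded from that face.
shift_replicate <- function(mask, axis, by) {
  d <- dim(mask)
  idx <- seq_len(d[axis]) - by
  idx <- pmin(pmax(idx, 1L), d[axis])
  switch(axis,
         mask[idx, , , drop = FALSE],
         mask[, idx, , drop = FALSE],
         mask[, , idx, drop = FALSE])
}

erode_mask <- function(mask, iterations = 1L) {
  for (i in seq_len(iterations)) {
    out <- mask
    for (axis in 1:3) for (by in c(-1L, 1L))
      out <- out & shift_replicate(mask, axis, by)
    mask <- out
  }
  mask
}

dilate_mask <- function(mask, iterations = 1L) {
  for (i in seq_len(iterations)) {
    out <- mask
    for (axis in 1:3) for (by in c(-1L, 1L))
      out <- out | shift_replicate(mask, axis, by)
    mask <- out
  }
  mask
}
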