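test_that("forward projection matches the closed-form disc chord length", {
  # uniform disc value v, radius R: central ray integral = v * 2R
  v <- 3.7; R <- 40
  disc <- disc_volume(v, R, n = 128, nz = 1, spacing = c(1, 1, 2))
  g <- sino_geometry(n_radial = 128, radial_spacing = 1, n_angles = 12,
                     n_slices = 1, slice_spacing = 2)
  sino <- forward_project(disc, g)
  centre_bins <- c(64, 65)  # +/- 0.5 mm offset from the axis
  for (a in c(1, 4, 7)) {
    expect_equal(sino$data[a, centre_bins[1], 1], v * 2 * R,
                 tolerance = 0.01)
    expect_equal(sino$data[a, centre_bins[2], 1], v * 2 * R,
                 tolerance = 0.01)
  }
  # off-centre ray at offset s: chord = 2 sqrt(R^2 - s^2)
  s_off <- sino_radial_offsets(g)[85]
  expect_equal(sino$data[1, 85, 1], v * 2 * sqrt(R^2 - s_off^2),
               tolerance = 0.015)
})

test_that("forward projection is linear", {
  g <- small_geometry(n_slices = 2)
  zero <- voxel_volume(array(0, c(64, 64, 2)), c(2, 2, 2))
  expect_true(all(forward_project(zero, g)$data == 0))
  set.seed(11)
  xa <- array(runif(64 * 64 * 2), c(64, 64, 2))
  xb <- array(runif(64 * 64 * 2), c(64, 64, 2))
  X <- voxel_volume(xa, c(2, 2, 2)); Y <- voxel_volume(xb, c(2, 2, 2))
  XY <- voxel_volume(2.5 * xa - 1.25 * xb, c(2, 2, 2))
  lhs <- forward_project(XY, g)$data
  rhs <- 2.5 * forward_project(X, g)$data -
    1.25 * forward_project(Y, g)$data
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("backprojector is the exact adjoint of the forward projector", {
  g <- small_geometry()
  grid <- voxel_volume(array(0, c(64, 64, 4)), c(2, 2, 2))
  set.seed(101)
  for (i in 1:20) {
    x <- voxel_volume(array(runif(64 * 64 * 4), c(64, 64, 4)), c(2, 2, 2))
    y <- sinogram(array(runif(48 * 96 * 4), c(48, 96, 4)), g,
                  "line_integrals")
    lhs <- sum(forward_project(x, g)$data * y$data)
    rhs <- sum(x$data * back_project(y, grid)$data)
    expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)
  }
})

test_that("backprojection of ones is positive inside the field of view and zero maps to zero", {
  g <- small_geometry(n_slices = 1)
  grid <- voxel_volume(array(0, c(64, 64, 1)), c(2, 2, 2))
  bp <- back_project(sinogram(array(1, c(48, 96, 1)), g, "line_integrals"),
                     grid)
  xs <- voxel_centers(grid, 1); ys <- voxel_centers(grid, 2)
  inside <- outer(xs^2, ys^2, `+`) <= (0.9 * sino_fov_radius(g))^2
  expect_true(all(bp$data[, , 1][inside] > 0))
  bp0 <- back_project(sinogram(array(0, c(48, 96, 1)), g, "line_integrals"),
                      grid)
  expect_true(all(bp0$data == 0))
})

test_that("ACF matches closed forms on discs and skull-like annuli", {
  mu_soft <- 0.0096; mu_bone <- 0.0151
  disc <- disc_volume(mu_soft, 100, n = 256, nz = 1, spacing = c(1, 1, 2),
                      kind = "mu")
  g <- sino_geometry(n_radial = 128, radial_spacing = 2, n_angles = 8,
                     n_slices = 1, slice_spacing = 2)
  acf <- compute_acf(disc, g)
  expect_equal(acf$data[1, 64, 1], exp(1.92), tolerance = 0.01)
  expect_true(all(acf$data >= 1))

  # soft core (R=80) + bone shell (80-90): central-ray two-chord value
  core <- disc_volume(mu_soft, 80, n = 256, nz = 1, spacing = c(1, 1, 2),
                      kind = "mu")
  shell <- annulus_volume(mu_bone, 80, 90, n = 256, spacing = c(1, 1, 2))
  head <- voxel_volume(core$data + shell$data, c(1, 1, 2), kind = "mu")
  acf2 <- compute_acf(head, g)
  analytic <- exp(mu_soft * 160 + mu_bone * 20)
  expect_equal(acf2$data[1, 64, 1], analytic, tolerance = 0.01)

  # zero attenuation -> ACF identically one; mu x2 -> ACF squared
  zero <- voxel_volume(array(0, dim(disc$data)), disc$spacing, kind = "mu")
  expect_true(all(compute_acf(zero, g)$data == 1))
  twice <- voxel_volume(2 * disc$data, disc$spacing, kind = "mu")
  expect_equal(compute_acf(twice, g)$data, acf$data^2, tolerance = 1e-10)
})

test_that("a centred point-like source projects near-constantly across angles", {
  # quasi-point: a small isotropic Gaussian blob (a bare single voxel has a
  # direction-dependent chord length through its square footprint)
  n <- 65
  xs <- (seq_len(n) - 33) * 2
  blob <- exp(-outer(xs^2, xs^2, `+`) / (2 * 3^2))
  vol <- voxel_volume(array(blob, c(n, n, 1)), c(2, 2, 2))
  g <- sino_geometry(n_radial = 95, radial_spacing = 2, n_angles = 24,
                     n_slices = 1, slice_spacing = 2)
  sino <- forward_project(vol, g)
  peak <- apply(sino$data[, , 1], 1, max)
  expect_lt(diff(range(peak)) / mean(peak), 0.05)
  # and its projected mass is angle-independent up to interpolation error
  mass <- rowSums(sino$data[, , 1]) * g$radial_spacing
  expect_lt(diff(range(mass)) / mean(mass), 0.01)
})

test_that("a field of view smaller than the volume support is rejected", {
  disc <- disc_volume(1, 60, n = 64, nz = 1)
  g_small <- sino_geometry(n_radial = 32, radial_spacing = 2, n_angles = 8,
                           n_slices = 1, slice_spacing = 2)
  expect_error(forward_project(disc, g_small), "field of view")
  expect_error(compute_acf(voxel_volume(-disc$data, disc$spacing),
                           small_geometry(n_slices = 1)),
               "non-negative")
})

test_that("normalization sinograms follow their mode contract", {
  g <- small_geometry(n_slices = 2)
  u <- make_normalization(g, "uniform")
  expect_true(all(u$data == 1))
  e1 <- make_normalization(g, "seeded_efficiency", seed = 9)
  e2 <- make_normalization(g, "seeded_efficiency", seed = 9)
  expect_identical(e1$data, e2$data)
  expect_true(all(e1$data >= 0.9 & e1$data <= 1.1))
  e3 <- make_normalization(g, "seeded_efficiency", seed = 10)
  expect_false(identical(e1$data, e3$data))
})

test_that("sinogram role invariants are enforced", {
  g <- small_geometry(n_slices = 1)
  d <- array(1, c(48, 96, 1))
  expect_error(sinogram(d - 2, g, "counts"), "non-negative")
  expect_error(sinogram(d + 0.5, g, "counts"), "integers")
  expect_error(sinogram(d * 0.5, g, "acf"), ">= 1")
  expect_error(sinogram(d * 0, g, "normalization"), "positive")
  expect_error(sinogram(array(1, c(10, 10, 1)), g, "counts"), "dimensions")
})

test_that("sinogram containers round-trip and export a CSV slice", {
  g <- small_geometry(n_slices = 2)
  set.seed(5)
  s <- sinogram(array(rpois(48 * 96 * 2, 7), c(48, 96, 2)), g, "counts")
  path <- withr::local_tempfile(fileext = ".sino")
  write_sinogram(s, path)
  s2 <- read_sinogram(path)
  expect_identical(s2$data, s$data)
  expect_identical(s2$role, "counts")
  expect_true(same_geometry_for_test(s2$geometry, g))
  csv <- withr::local_tempfile(fileext = ".csv")
  export_sinogram_csv(s, csv, slice = 2)
  df <- read.csv(csv)
  expect_identical(nrow(df), 48L * 96L)
  expect_equal(df$value, as.vector(s$data[, , 2]))
})
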