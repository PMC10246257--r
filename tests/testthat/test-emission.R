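test_that("lesion activity volumes follow the absolute and LBR rules", {
  b <- small_phantom()
  spec_abs <- lesion_spec("sphere", center = c(20, 14, 0), radius = 6,
                          activity = 10, psf_fwhm = 0)
  les <- lesion_activity_volume(spec_abs, b$atlas)
  mask <- lesion_mask(spec_abs, b$atlas)
  expect_identical(les$data, 10 * (mask$data + 0))  # exactly 10 * mask

  # LBR rule: value = (background mean over mask) x ratio, before smoothing
  spec_lbr <- lesion_spec("sphere", center = c(20, 14, 0), radius = 6,
                          lbr = 2, psf_fwhm = 0)
  les2 <- lesion_activity_volume(spec_lbr, b$atlas, b$activity)
  bg_mean <- mean(b$activity$data[mask$data == 1L])
  expect_equal(max(les2$data), 2 * bg_mean, tolerance = 1e-12)

  # atlas-ROI lesion covers exactly its region
  spec_roi <- lesion_spec("atlas_roi", label = 7L, activity = 5,
                          psf_fwhm = 0)
  les3 <- lesion_activity_volume(spec_roi, b$atlas)
  expect_identical(les3$data > 0, b$atlas$data == 7L)
})

test_that("PSF smoothing conserves total lesion activity away from edges", {
  b <- generate_phantom(seed = 1)  # 128^2 grid: lesion far from edges
  spec <- lesion_spec("sphere", center = c(20, 14, 0), radius = 6,
                      activity = 10, psf_fwhm = 4)
  raw <- lesion_activity_volume(
    lesion_spec("sphere", center = c(20, 14, 0), radius = 6, activity = 10,
                psf_fwhm = 0), b$atlas)
  sm <- lesion_activity_volume(spec, b$atlas)
  expect_equal(sum(sm$data) * voxel_volume_mm3(sm),
               sum(raw$data) * voxel_volume_mm3(raw),
               tolerance = 0.005)
})

test_that("degenerate lesion definitions are rejected", {
  b <- small_phantom()
  far <- lesion_spec("sphere", center = c(500, 0, 0), radius = 4,
                     activity = 1)
  expect_error(suppressWarnings(lesion_activity_volume(far, b$atlas)),
               "empty")
  lbr_spec <- lesion_spec("sphere", center = c(20, 14, 0), radius = 4,
                          lbr = 2)
  expect_error(lesion_activity_volume(lbr_spec, b$atlas), "background")
  # zero background under the mask
  zero_bg <- voxel_volume(array(0, dim(b$activity$data)),
                          b$activity$spacing, b$activity$origin,
                          kind = "activity")
  expect_error(lesion_activity_volume(lbr_spec, b$atlas, zero_bg), "zero")
  expect_error(lesion_spec("sphere", center = c(0, 0, 0), radius = 4),
               "exactly one")
  expect_error(lesion_spec("sphere", center = c(0, 0, 0), radius = -1,
                           activity = 1), "radius")
})

test_that("the expected-counts chain collapses correctly when degenerate", {
  act <- disc_volume(10, 40, nz = 2)
  g <- small_geometry(n_slices = 2)
  mu0 <- voxel_volume(array(0, dim(act$data)), act$spacing, kind = "mu")
  m <- acquisition_model(g, compute_acf(mu0, g), scatter_fraction = 0,
                         duration_scale = 2.5)
  ec <- expected_counts(act, m)
  expect_equal(ec$data, 2.5 * forward_project(act, g)$data,
               tolerance = 1e-12)
  # doubling the duration scale doubles every bin
  m2 <- acquisition_model(g, compute_acf(mu0, g), scatter_fraction = 0,
                          duration_scale = 5)
  expect_equal(expected_counts(act, m2)$data, 2 * ec$data,
               tolerance = 1e-12)
})

test_that("the scatter model enforces the global scatter fraction exactly", {
  acq <- disc_acquisition(scatter_fraction = 0.3)
  sf <- sum(acq$scatter$data) / sum(acq$expected$data)
  expect_equal(sf, 0.3, tolerance = 1e-6)
  expect_true(all(acq$expected$data >= 0))
})

test_that("expectation is linear in activity", {
  acq <- disc_acquisition()
  twice <- voxel_volume(2 * acq$activity$data, acq$activity$spacing,
                        kind = "activity")
  expect_equal(expected_counts(twice, acq$model)$data, 2 * acq$expected$data,
               tolerance = 1e-9)
})

test_that("Poisson noise has the right moments and is seed-reproducible", {
  g <- sino_geometry(n_radial = 100, radial_spacing = 2, n_angles = 100,
                     n_slices = 10, slice_spacing = 2)  # 1e5 bins
  expected <- sinogram(array(100, c(100, 100, 10)), g, "expected_counts")
  counts <- add_poisson(expected, seed = 123)
  n_bins <- length(counts$data)
  expect_identical(n_bins, 100000L)
  expect_lt(abs(mean(counts$data) - 100), 3 * sqrt(100 / n_bins))
  vm <- stats::var(as.vector(counts$data)) / mean(counts$data)
  expect_gt(vm, 0.97); expect_lt(vm, 1.03)
  expect_identical(add_poisson(expected, seed = 123)$data, counts$data)
  expect_false(identical(add_poisson(expected, seed = 124)$data,
                         counts$data))
  zero <- sinogram(array(0, c(100, 100, 10)), g, "expected_counts")
  expect_true(all(add_poisson(zero, seed = 1)$data == 0))
})

test_that("compose follows the add / replace / lesion_only contracts", {
  acq <- disc_acquisition()
  g <- acq$geometry
  background <- add_poisson(acq$expected, seed = 3)
  lesion_act <- disc_volume(20, 10, nz = 4)
  lesion_exp <- expected_counts(lesion_act, acq$model)

  # zero lesion, add mode -> identity
  zero_les <- sinogram(array(0, dim(background$data)), g, "expected_counts")
  expect_identical(compose(background, zero_les, "add", seed = 4)$data,
                   background$data)

  # add: exact integer accounting against the same-seed lesion draw
  added <- compose(background, lesion_exp, "add", seed = 4)
  lesion_draw <- add_poisson(lesion_exp, seed = 4)
  expect_identical(sum(added$data),
                   sum(background$data) + sum(lesion_draw$data))

  # lesion_only ignores any supplied background
  only_a <- compose(background, lesion_exp, "lesion_only", seed = 4)
  only_b <- compose(NULL, lesion_exp, "lesion_only", seed = 4)
  expect_identical(only_a$data, only_b$data)

  # replace touches no bin outside the lesion projection support
  support <- lesion_support_mask(lesion_exp)
  rep <- compose(background, lesion_exp, "replace", seed = 4)
  expect_identical(rep$data[!support], background$data[!support])
  expect_identical(rep$data[support], lesion_draw$data[support])

  expect_error(compose(NULL, lesion_exp, "add"), "background")
  expect_error(compose(NULL, lesion_exp, "replace"), "background")
})
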