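# Small in-code fixtures shared across test files.

same_geometry_for_test <- function(a, b) {
  a$n_radial == b$n_radial && a$n_angles == b$n_angles &&
    a$n_slices == b$n_slices &&
    isTRUE(all.equal(a$radial_spacing, b$radial_spacing)) &&
    isTRUE(all.equal(a$slice_spacing, b$slice_spacing))
}

# Uniform disc volume: value v inside radius R (mm), on an n x n x nz grid
# centred on the world origin.
disc_volume <- function(value = 1, radius = 40, n = 64, nz = 4,
                        spacing = c(2, 2, 2), kind = "activity") {
  xs <- (seq_len(n) - 1 - (n - 1) / 2) * spacing[1]
  ys <- (seq_len(n) - 1 - (n - 1) / 2) * spacing[2]
  r <- sqrt(outer(xs^2, ys^2, `+`))
  voxel_volume(array(value * (r <= radius), c(n, n, nz)), spacing,
               kind = kind)
}

# Annulus (shell) volume: value inside (r_in, r_out].
annulus_volume <- function(value, r_in, r_out, n = 64, nz = 1,
                           spacing = c(2, 2, 2), kind = "mu") {
  xs <- (seq_len(n) - 1 - (n - 1) / 2) * spacing[1]
  r <- sqrt(outer(xs^2, xs^2, `+`))
  voxel_volume(array(value * (r > r_in & r <= r_out), c(n, n, nz)),
               spacing, kind = kind)
}

small_geometry <- function(n_angles = 48, n_radial = 96, n_slices = 4,
                           spacing = 2) {
  sino_geometry(n_radial = n_radial, radial_spacing = spacing,
                n_angles = n_angles, n_slices = n_slices,
                slice_spacing = spacing)
}

# Compact phantom for driver-level tests: full shell anatomy on a 96^2 grid.
small_phantom <- function(seed = 1, nz = 4) {
  generate_phantom(seed = seed, grid = c(96, 96, nz), spacing = c(2, 2, 2),
                   n_rois = 8)
}

# Matched noiseless acquisition on a disc: returns model, expected counts,
# and the separated scatter expectation (for use as the recon estimate).
disc_acquisition <- function(value = 10, radius = 40, mu_radius = 50,
                             scatter_fraction = 0.3, duration_scale = 1e-3,
                             n = 64, nz = 4) {
  act <- disc_volume(value, radius, n = n, nz = nz)
  mu <- disc_volume(0.0096, mu_radius, n = n, nz = nz, kind = "mu")
  g <- small_geometry(n_slices = nz)
  model <- acquisition_model(g, compute_acf(mu, g),
                             scatter_fraction = scatter_fraction,
                             duration_scale = duration_scale)
  ec <- expected_counts(act, model)
  trues <- duration_scale * model$norm$data *
    forward_project(act, g)$data / model$acf$data
  scatter <- sinogram(ec$data - trues, g, "scatter")
  list(activity = act, mu = mu, geometry = g, model = model,
       expected = ec, scatter = scatter)
}
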