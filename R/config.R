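#' Default configuration
#'
#' A single nested list gathering every tunable parameter of the pipeline:
#' tissue LACs, HU-to-LAC breakpoints, sinogram geometry, reconstruction
#' settings, the degradation parameters of the MRAC-like variants, and the
#' emission model. Used as the base that a user YAML config (see
#' [read_config()]) is merged onto.
#' @return a nested list.
#' @export
default_config <- function() {
  mu <- tissue_mu_defaults()
  list(
    phantom = list(grid = c(128, 128, 16), spacing = c(2, 2, 2), n_rois = 8,
                   radii = c(brain = 78, skull_outer = 86, scalp_outer = 92),
                   activity_background = 5000, scalp_activity_fraction = 0.25),
    tissue_mu = as.list(mu),
    hu_lac_breakpoints = default_hu_lac_breakpoints(),
    geometry = list(n_radial = 192, radial_spacing = 2, n_angles = 96),
    recon = list(n_iterations = 3, n_subsets = 24, post_filter_fwhm = 4),
    emission = list(scatter_fraction = 0.3, duration_scale = 1e-4,
                    scatter_fwhm = 80, psf_fwhm = 4),
    mrac = list(dixonbone_scale = 0.95, dixonbone_erosion = 1,
                ute_flip_fraction = 0.20, ute_bone_mu = mu[["ute_bone"]],
                dldixon_noise_sigma_frac = 0.01),
    lesions = list(radius = 4, lbr = 2),
    seeds = 1:11)
}

#' Read a YAML configuration file
#'
#' Values present in the file override the matching entries of
#' [default_config()]; everything else keeps its default.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return a nested list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  modify_list_deep(cfg, user)
}

modify_list_deep <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.data.frame(base[[nm]])) {
      base[[nm]] <- modify_list_deep(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}
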