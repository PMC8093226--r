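# Package configuration. Every numeric constant used by the pipeline's design
# decisions lives here so it can be overridden from a single YAML file whose
# sections mirror the module names.

#' Default pipeline configuration
#'
#' @return Nested list with sections `io`, `synthetic`, `segmentation`,
#'   `shape`, `graphs`, `texture`, `stability`, `model`, `robustness`.
#' @export
default_config <- function() {
  list(
    io = list(
      missing_sentinel = NA_real_
    ),
    synthetic = list(
      canvas_px = 1024L,
      mpp = 1.0,
      min_spacing_factor = 1.2,
      boundary_vertices = 64L,
      max_place_attempts = 200L
    ),
    segmentation = list(
      analysis_mpp = 1.0,
      min_area_um2 = 40,
      opening_radius_px = 2L,
      min_region_fraction = 0.01
    ),
    shape = list(
      n_boundary = 128L,
      n_fd = 10L,
      hu_log_compress = TRUE,
      p5_p95_as_ratio = TRUE
    ),
    graphs = list(
      density_radii_um = c(50, 100),
      subgraph_eps_factor = 2.0
    ),
    texture = list(
      n_levels = 32L,
      distance_px = 1L,
      min_region_um2 = 64^2
    ),
    stability = list(
      ks_tau = 0.4,
      min_regions_per_site = 10L
    ),
    model = list(
      alpha = 0.5,
      nfolds = 10L,
      threshold_quantiles = c(0.1, 0.9),
      threshold_rule = "logrank",
      bcr_psa_cut = 0.2,
      min_followup_days = 30
    ),
    robustness = list(
      n_layers = 10L
    )
  )
}

#' Load configuration from YAML, merged over the defaults
#'
#' @param path YAML file whose top-level sections mirror [default_config()].
#' @return Merged configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  merge_lists(cfg, user)
}

merge_lists <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_lists(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}
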