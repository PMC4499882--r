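#' Default run configuration
#'
#' Nested list of every tunable parameter of the pipeline, with defaults
#' encoding the standard study conditions: Poisson ratio 0.2, a 2 mm
#' cylindrical gel domain, 50 um near/far bead classification threshold,
#' 2 h sampling interval, 4e-4 beads/um^3. Unknown keys in a user config are
#' rejected to prevent silent typos.
#'
#' @return Named nested list.
#' @export
default_config <- function() {
  list(
    material = list(E = 500, nu = 0.2),
    mesh = list(gel_radius = 1000, gel_height = 2000, n_layers = 8, order = 2),
    scene = list(a = 50, p = 100, box_halfwidth = 100, bead_density = 4e-4,
                 noise_sigma = 0.1),
    interpolation = list(method = "gaussian", length_scale = NULL, ridge = 1e-8),
    ccf = list(max_lag = 5, estimator = "biased", sd_denom = "n-1"),
    alignment = list(subregion_size = 8, stride = 16, coherence_min = 0.2,
                     n_bins = 18),
    thresholds = list(near_far_um = 50),
    series = list(duration = 40, dt = 2),
    masks = list(n_tissues = 50, image_size = 96, base_radius = 20),
    output = list(dir = "tfm3d-out")
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML config and merges it over [default_config()]; any key absent
#' from the defaults is an error.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return Validated config list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  merge_validate(cfg, user, prefix = "")
}

merge_validate <- function(base, user, prefix) {
  if (!is.list(user)) abort(sprintf("config section '%s' must be a mapping", prefix))
  for (key in names(user)) {
    full <- if (nzchar(prefix)) paste0(prefix, ".", key) else key
    if (!key %in% names(base)) {
      abort(sprintf("unknown config key: '%s'", full))
    }
    if (is.list(base[[key]])) {
      base[[key]] <- merge_validate(base[[key]], user[[key]], full)
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}
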