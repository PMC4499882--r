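#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy and glance methods
#'
#' Broom-style accessors: `tidy()` returns the per-observation table of a
#' result object, `glance()` a one-row summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name tfm3d-broom
NULL

#' @rdname tfm3d-broom
#' @export
tidy.cross_correlation <- function(x, ...) as_tibble(x)

#' @rdname tfm3d-broom
#' @export
glance.cross_correlation <- function(x, ...) {
  pk <- peak_correlation(x)
  tibble(n = attr(x, "n"), peak_lag = pk$peak_lag, peak_r = pk$peak_r,
         r0 = x$ccor[x$lag == 0])
}

#' @rdname tfm3d-broom
#' @export
tidy.alignment_stats <- function(x, ...) {
  if (is.null(x$delta_theta)) {
    tibble(term = c("mean_angle", "R", "p_rayleigh"),
           estimate = c(x$mean_angle, x$R, x$p_rayleigh))
  } else {
    tibble(term = c("mean_angle", "R", "p_rayleigh", "delta_theta_median"),
           estimate = c(x$mean_angle, x$R, x$p_rayleigh, x$delta_theta_median))
  }
}

#' @rdname tfm3d-broom
#' @export
glance.alignment_stats <- function(x, ...) {
  tibble(n = x$n, mean_angle = x$mean_angle, R = x$R,
         p_rayleigh = x$p_rayleigh)
}

#' @rdname tfm3d-broom
#' @export
tidy.correlation_report <- function(x, ...) x$per_bead

#' @rdname tfm3d-broom
#' @export
glance.correlation_report <- function(x, ...) {
  near <- x$class_summary[x$class_summary$class == "near", ]
  far <- x$class_summary[x$class_summary$class == "far", ]
  tibble(mean_peak_r_near = near$mean_peak_r, mean_peak_r_far = far$mean_peak_r,
         p_value = x$p_value)
}

#' @rdname tfm3d-broom
#' @export
tidy.invasion_angles <- function(x, ...) x$angles

#' @rdname tfm3d-broom
#' @export
glance.invasion_angles <- function(x, ...) {
  tibble(n = x$n, circular_mean = x$circular_mean, R = x$R,
         p_rayleigh = if (is.null(x$rayleigh)) NA_real_ else x$rayleigh$p.value)
}

#' @rdname tfm3d-broom
#' @export
glance.fem_solution <- function(x, ...) {
  tibble(n_nodes = nrow(x$U), n_elements = nrow(x$mesh$elements),
         order = x$mesh$order, max_u = max(sqrt(rowSums(x$U^2))))
}

#' @rdname tfm3d-broom
#' @export
tidy.traction_field <- function(x, ...) as_tibble(x)

#' @rdname tfm3d-broom
#' @export
glance.traction_field <- function(x, ...) {
  tibble(n_nodes = nrow(x), median_t = median(x$t_mag),
         mean_t = mean(x$t_mag), max_t = max(x$t_mag),
         tensile_fraction = mean(x$t_n > 0))
}
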