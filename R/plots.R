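#' Rose plot of an orientation histogram
#'
#' Axial rose diagram (each orientation drawn at theta and theta + 180) with
#' an optional reference direction.
#'
#' @param object An [orientation_histogram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.orientation_histogram <- function(object, ...) {
  df <- as_tibble(object)
  df2 <- bind_rows(df, mutate(df, bin_mid = .data$bin_mid + 180))
  p <- ggplot2::ggplot(df2, ggplot2::aes(x = .data$bin_mid, y = .data$count)) +
    ggplot2::geom_col(width = 180 / nrow(df), fill = "steelblue",
                      colour = "grey30", linewidth = 0.2) +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 330, by = 30)) +
    ggplot2::labs(x = "fiber orientation (deg)", y = "count") +
    ggplot2::theme_minimal()
  ref <- attr(object, "reference_angle")
  if (!is.null(ref)) {
    p <- p + ggplot2::geom_vline(xintercept = ref %% 360, colour = "red")
  }
  p
}

#' Stem plot of a cross-correlation function
#'
#' @param object A [cross_covariance()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cross_correlation <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$lag, y = .data$ccor)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$lag, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "lag (samples)", y = "cross-correlation r") +
    ggplot2::theme_minimal()
}

#' Heat map of an invasion frequency map
#'
#' @param object A [frequency_map()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.frequency_map <- function(object, ...) {
  m <- unclass(object)
  attr(m, "n_tissues") <- NULL
  df <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$frequency <- as.vector(m)[(df$col - 1L) * nrow(m) + df$row]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = nrow(m) - .data$row + 1,
                                   fill = .data$frequency)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", fill = "frequency") +
    ggplot2::theme_minimal()
}

#' Traction magnitude over the tissue surface
#'
#' Scatter of interface nodes in a polar-angle unrolling, coloured by
#' traction magnitude; a quick look at where traction localizes.
#'
#' @param object A [surface_tractions()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.traction_field <- function(object, ...) {
  ctr <- colMeans(object[, c("x", "y", "z")])
  df <- mutate(as_tibble(object),
               azimuth = rad2deg(atan2(.data$y - ctr[2], .data$x - ctr[1])),
               polar = rad2deg(acos(pmin(pmax(
                 (.data$z - ctr[3]) /
                   sqrt((.data$x - ctr[1])^2 + (.data$y - ctr[2])^2 +
                          (.data$z - ctr[3])^2), -1), 1))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$azimuth, y = .data$polar,
                                   colour = .data$t_mag)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "azimuth (deg)", y = "polar angle (deg)",
                  colour = "|t| (Pa)") +
    ggplot2::theme_minimal()
}
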