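#' Sample cross-covariance and cross-correlation of two time series
#'
#' For series `x_t, y_t` of equal length `n`, the lag-`k` sample
#' cross-covariance is
#' \deqn{c_{xy}(k) = \frac{1}{n} \sum_t (x_t - \bar x)(y_{t+k} - \bar y)}
#' (sum over the `n - |k|` overlapping terms; full-series means), and the
#' cross-correlation coefficient is `r_xy(k) = c_xy(k) / (s_x s_y)` with the
#' sample standard deviations of the two series. The `1/n` (biased) estimator
#' with `1/(n-1)` standard deviations is the default convention, matching
#' common statistical software; `estimator = "unbiased"` divides by
#' `n - |k|` instead, and `sd_denom = "n"` uses `1/n` standard deviations
#' (with which `r_xx(0) = 1` exactly).
#'
#' @param x,y Equal-length numeric series.
#' @param max_lag Maximum lag in samples; requires `n >= 2 * max_lag + 2`.
#' @param estimator `"biased"` (1/n) or `"unbiased"` (1/(n-|k|)).
#' @param sd_denom `"n-1"` (default) or `"n"`.
#' @return A `cross_correlation` tibble: `lag, ccov, ccor`, with attributes
#'   `n`, `means`, `sds`.
#' @export
cross_covariance <- function(x, y, max_lag = 5L,
                             estimator = c("biased", "unbiased"),
                             sd_denom = c("n-1", "n")) {
  estimator <- match.arg(estimator)
  sd_denom <- match.arg(sd_denom)
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) abort("`x` and `y` must have equal length")
  max_lag <- as.integer(max_lag)
  if (n < 2L * max_lag + 2L) abort("series too short for `max_lag`")
  if (!all(is.finite(x)) || !all(is.finite(y))) abort("series must be finite")
  xm <- x - mean(x); ym <- y - mean(y)
  sx <- sqrt(sum(xm^2) / if (sd_denom == "n-1") (n - 1) else n)
  sy <- sqrt(sum(ym^2) / if (sd_denom == "n-1") (n - 1) else n)
  if (sx == 0 || sy == 0) abort("zero-variance series: correlation undefined")
  lags <- (-max_lag):max_lag
  ccov <- vapply(lags, function(k) {
    if (k >= 0) {
      t1 <- seq_len(n - k)
      s <- sum(xm[t1] * ym[t1 + k])
    } else {
      t1 <- seq_len(n + k) - k   # t in (|k|+1)..n, pairs x_t y_{t+k}
      s <- sum(xm[t1] * ym[t1 + k])
    }
    s / if (estimator == "biased") n else (n - abs(k))
  }, numeric(1))
  out <- tibble(lag = lags, ccov = ccov, ccor = ccov / (sx * sy))
  attr(out, "n") <- n
  attr(out, "means") <- c(x = mean(x), y = mean(y))
  attr(out, "sds") <- c(x = sx, y = sy)
  class(out) <- c("cross_correlation", class(out))
  out
}

#' Peak of a cross-correlation
#'
#' @param cc A [cross_covariance()] result.
#' @return One-row tibble `peak_lag, peak_r`: the lag maximizing `r_xy`.
#' @export
peak_correlation <- function(cc) {
  i <- which.max(cc$ccor)
  tibble(peak_lag = cc$lag[i], peak_r = cc$ccor[i])
}

#' Classify beads as near or far from the cohort
#'
#' Labels each bead by its minimum distance to the cohort (given as a set of
#' points tracing the cohort over the observation window): `< threshold` um
#' is `"near"`, otherwise `"far"`. Distances exactly at the threshold are
#' labelled `"far"` (the classes are strict inequalities; the boundary case
#' must go somewhere and is documented here).
#'
#' @param beads Tibble with `bead_id, x, y, z` (um); repeated positions per
#'   bead are allowed (the minimum over rows is used).
#' @param cohort_points n x 3 matrix or data frame: points on/inside the
#'   cohort over the window (um).
#' @param threshold Near/far cutoff, um; default 50.
#' @return Tibble `bead_id, min_distance, class`.
#' @export
classify_beads <- function(beads, cohort_points, threshold = 50) {
  cp <- as_point_matrix(cohort_points, "cohort_points")
  pts <- as_point_matrix(beads)
  D2 <- outer(rowSums(pts^2), rowSums(cp^2), `+`) - 2 * pts %*% t(cp)
  d <- sqrt(pmax(apply(D2, 1, min), 0))
  tibble(bead_id = beads$bead_id, dist = d) %>%
    group_by(.data$bead_id) %>%
    summarise(min_distance = min(.data$dist), .groups = "drop") %>%
    mutate(class = ifelse(.data$min_distance < threshold, "near", "far"))
}

#' Scalar bead displacement series
#'
#' Converts bead tracks into per-bead scalar displacement time series,
#' either the signed projection of the displacement vector onto the
#' bead-to-cohort direction (default; positive = toward the cohort, which
#' carries the "in phase with extension" information) or the raw magnitude.
#'
#' @param field A [displacements_from_tracks()] result (all times).
#' @param toward Length-3 point the projection axis points to (e.g. the
#'   cohort tip), um; required for `mode = "projection"`.
#' @param mode `"projection"` or `"magnitude"`.
#' @return Tibble `bead_id, t, displacement` (um).
#' @export
bead_displacement_series <- function(field, toward = NULL,
                                     mode = c("projection", "magnitude")) {
  mode <- match.arg(mode)
  if (mode == "projection") {
    if (is.null(toward)) abort("`toward` is required for projection mode")
    toward <- as.numeric(toward)
    dx <- toward[1] - field$x; dy <- toward[2] - field$y; dz <- toward[3] - field$z
    nrm <- sqrt(dx^2 + dy^2 + dz^2)
    disp <- (field$ux * dx + field$uy * dy + field$uz * dz) / nrm
  } else {
    disp <- sqrt(field$ux^2 + field$uy^2 + field$uz^2)
  }
  tibble(bead_id = field$bead_id, t = field$t, displacement = disp)
}

#' Near/far correlation report for cohort-matrix coupling
#'
#' Cross-correlates the cohort length series against every bead's scalar
#' displacement series, extracts each bead's peak correlation and its lag,
#' and contrasts the peak correlations of near vs far beads with Welch's
#' t-test. Both series are first-differenced by default so that the
#' comparison concerns length *variations* rather than the shared growth
#' trend.
#'
#' @param cohort Tibble `t, length` (a `coupled_series$cohort` works).
#' @param bead_series Tibble `bead_id, class, t, displacement` with classes
#'   `"near"` and `"far"`.
#' @param max_lag Maximum lag, samples.
#' @param detrend `"difference"` (first differences, default) or `"none"`.
#' @param ... Passed to [cross_covariance()].
#' @return A `correlation_report`: list with `per_bead` (tibble `bead_id,
#'   class, peak_r, peak_lag`), `class_summary`, `welch` (htest), `p_value`.
#' @export
near_far_correlation_report <- function(cohort, bead_series, max_lag = 5L,
                                        detrend = c("difference", "none"),
                                        ...) {
  detrend <- match.arg(detrend)
  if (!all(c("near", "far") %in% bead_series$class)) {
    abort("`bead_series` must contain both near and far beads")
  }
  prep <- function(v) if (detrend == "difference") diff(v) else v
  x <- prep(cohort$length)
  per_bead <- bead_series %>%
    group_by(.data$bead_id, .data$class) %>%
    arrange(.data$t, .by_group = TRUE) %>%
    summarise(series = list(prep(.data$displacement)), .groups = "drop") %>%
    mutate(pk = purrr::map(.data$series, function(yv) {
      peak_correlation(cross_covariance(x, yv, max_lag = max_lag, ...))
    })) %>%
    tidyr::unnest("pk") %>%
    select("bead_id", "class", "peak_r", "peak_lag")
  counts <- table(per_bead$class)
  if (any(counts < 3L)) {
    abort("need at least 3 beads per class for the near/far contrast")
  }
  zero_var <- per_bead %>%
    group_by(.data$class) %>%
    summarise(v = var(.data$peak_r), .groups = "drop")
  if (any(zero_var$v < 1e-12)) {
    warn("a class has (near-)zero variance in peak correlation")
  }
  welch <- t.test(peak_r ~ class, data = per_bead,
                  alternative = "less")  # H1: far < near
  cs <- per_bead %>%
    group_by(.data$class) %>%
    summarise(n = dplyr::n(), mean_peak_r = mean(.data$peak_r),
              sd_peak_r = sd(.data$peak_r),
              modal_lag = .data$peak_lag[which.max(tabulate(match(
                .data$peak_lag, unique(.data$peak_lag))))],
              .groups = "drop")
  structure(
    list(per_bead = per_bead, class_summary = cs, welch = welch,
         p_value = welch$p.value),
    class = "correlation_report"
  )
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("<correlation_report>\n")
  print(x$class_summary)
  cat(sprintf("Welch one-sided (far < near) p = %.3g\n", x$p_value))
  invisible(x)
}

#' Cohort length from a binary mask
#'
#' Distance from the original tissue edge to the tip of the migrating
#' cohort. The edge is a line given as `list(point = c(x, y), normal =
#' c(nx, ny))` in pixel coordinates (y up, normal pointing toward the cohort
#' side); pixels with positive signed distance belong to the cohort.
#' `method = "euclidean"` returns the maximum perpendicular distance from
#' the edge; `"geodesic"` measures along the cohort (8-connected shortest
#' path from the edge), appropriate for bent cohorts.
#'
#' @param mask Logical matrix.
#' @param edge Edge line, see above.
#' @param pixel_size um/px.
#' @param method `"euclidean"` or `"geodesic"`.
#' @return Length in um (0, with a warning, if no cohort pixels lie beyond
#'   the edge).
#' @export
cohort_length <- function(mask, edge, pixel_size = 1,
                          method = c("euclidean", "geodesic")) {
  method <- match.arg(method)
  stopifnot(is.matrix(mask))
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    warn("empty mask: cohort length 0")
    return(0)
  }
  xs <- idx[, 2]; ys <- nrow(mask) - idx[, 1]   # y up
  nn <- edge$normal / sqrt(sum(edge$normal^2))
  d <- (xs - edge$point[1]) * nn[1] + (ys - edge$point[2]) * nn[2]
  beyond <- d > 0
  if (!any(beyond)) {
    warn("no cohort pixels beyond the edge: length 0")
    return(0)
  }
  if (method == "euclidean") {
    return(max(d) * pixel_size)
  }
  # geodesic: BFS over cohort pixels from the edge-adjacent seed band
  sel <- which(mask)
  dist_px <- rep(Inf, length(mask))
  lin <- (idx[, 2] - 1L) * nrow(mask) + idx[, 1]
  seed <- lin[beyond & d <= 1.5]
  if (length(seed) == 0L) seed <- lin[beyond][which.min(d[beyond])]
  dist_px[seed] <- d[match(seed, lin)]
  frontier <- seed
  nr <- nrow(mask)
  inmask <- logical(length(mask)); inmask[lin[beyond]] <- TRUE
  off <- c(-1, 1, -nr, nr, -nr - 1, -nr + 1, nr - 1, nr + 1)
  step <- c(1, 1, 1, 1, sqrt(2), sqrt(2), sqrt(2), sqrt(2))
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (k in seq_along(off)) {
      cand <- frontier + off[k]
      ok <- cand >= 1 & cand <= length(mask) & inmask[pmax(cand, 1)]
      # guard row wrap-around
      r0 <- (frontier - 1L) %% nr
      wrap <- (off[k] %in% c(-1, -nr - 1, nr - 1) & r0 == 0L) |
        (off[k] %in% c(1, -nr + 1, nr + 1) & r0 == nr - 1L)
      ok <- ok & !wrap
      nd <- dist_px[frontier] + step[k]
      upd <- ok & nd < dist_px[pmax(cand, 1)]
      if (any(upd)) {
        dist_px[cand[upd]] <- nd[upd]
        nxt <- c(nxt, cand[upd])
      }
    }
    frontier <- unique(nxt)
  }
  max(dist_px[is.finite(dist_px)]) * pixel_size
}

#' Projected area of a binary mask
#'
#' @param mask Logical matrix.
#' @param pixel_size um/px.
#' @return Area in um^2 (pixel count times `pixel_size^2`).
#' @export
projected_area <- function(mask, pixel_size = 1) {
  stopifnot(is.matrix(mask))
  sum(mask) * pixel_size^2
}

#' Pixel frequency map of replicate tissue masks
#'
#' Per-pixel fraction of masks in which the pixel is occupied; stacking
#' binarized images of replicate tissues of identical initial geometry
#' summarizes where collective invasion occurs.
#'
#' @param masks A `mask_stack` or list of equal-sized logical matrices.
#' @return A `frequency_map`: matrix of values `k / n`, with attribute
#'   `n_tissues`.
#' @export
frequency_map <- function(masks) {
  if (inherits(masks, "mask_stack")) masks <- masks$masks
  if (length(masks) == 0L) abort("no masks")
  dims <- dim(masks[[1]])
  for (m in masks) {
    if (!all(dim(m) == dims)) abort("all masks must have identical dimensions")
  }
  acc <- Reduce(`+`, lapply(masks, function(m) m * 1))
  out <- acc / length(masks)
  attr(out, "n_tissues") <- length(masks)
  class(out) <- c("frequency_map", class(out))
  out
}

#' Invasion angles of migrating cohorts from a mask stack
#'
#' Subtracts the common base geometry from each mask, labels the remaining
#' connected components (the migrating cohorts), and reports one directional
#' angle per cohort: the direction from the tissue centroid to the cohort's
#' farthest pixel (tip), in degrees `[0, 360)`, 0 = +x (east),
#' counter-clockwise. Includes the Rayleigh test of directional uniformity.
#'
#' @param masks A `mask_stack` or list of logical matrices.
#' @param base_shape Logical matrix of the common initial geometry (taken
#'   from the `mask_stack` if available).
#' @param min_pixels Minimum component size to count as a cohort.
#' @return An `invasion_angles` object: list with `angles` (tibble
#'   `tissue, angle, size`), `rayleigh` (htest), `circular_mean`, `R`, `n`.
#' @export
invasion_angles <- function(masks, base_shape = NULL, min_pixels = 10L) {
  if (inherits(masks, "mask_stack")) {
    if (is.null(base_shape)) base_shape <- masks$base_shape
    masks <- masks$masks
  }
  if (is.null(base_shape)) abort("`base_shape` is required")
  ctr <- mask_centroid(base_shape)
  nr <- nrow(base_shape)
  rows <- list()
  for (i in seq_along(masks)) {
    cohort <- masks[[i]] & !base_shape
    if (!any(cohort)) next
    lab <- EBImage::bwlabel(cohort)
    for (comp in seq_len(max(lab))) {
      idx <- which(lab == comp, arr.ind = TRUE)
      if (nrow(idx) < min_pixels) next
      xs <- idx[, 2] - ctr["x"]
      ys <- (nr - idx[, 1]) - (nr - ctr["y_row"])
      r <- sqrt(xs^2 + ys^2)
      # tip = centroid of the farthest pixel band (a single extreme pixel
      # would bias toward a corner of a blunt cohort front)
      band <- r >= max(r) - 2
      ang <- rad2deg(atan2(mean(ys[band]), mean(xs[band]))) %% 360
      rows[[length(rows) + 1L]] <- tibble(tissue = i, angle = ang,
                                          size = nrow(idx))
    }
  }
  if (length(rows) == 0L) {
    warn("no cohorts detected outside the base shape")
    return(structure(list(angles = tibble(tissue = integer(), angle = numeric(),
                                          size = integer()),
                          rayleigh = NULL, circular_mean = NA_real_,
                          R = NA_real_, n = 0L),
                     class = "invasion_angles"))
  }
  ang <- bind_rows(rows)
  cm <- circular_mean(ang$angle, axial = FALSE)
  ray <- if (nrow(ang) >= 2L) rayleigh_test(ang$angle, axial = FALSE)
  structure(list(angles = ang, rayleigh = ray, circular_mean = cm$mean,
                 R = cm$R, n = nrow(ang)),
            class = "invasion_angles")
}

#' @export
print.invasion_angles <- function(x, ...) {
  cat(sprintf("<invasion_angles> %d cohorts, circular mean %.1f deg, R = %.3f, Rayleigh p = %.3g\n",
              x$n, x$circular_mean, x$R,
              if (is.null(x$rayleigh)) NA else x$rayleigh$p.value))
  invisible(x)
}

#' Nuclear-to-cytoplasmic signal ratio
#'
#' Mean background-subtracted intensity inside the nuclear mask divided by
#' the mean over the cytoplasmic remainder (cell minus nucleus). Used to
#' quantify nuclear translocation of a transcription factor from a confocal
#' slice.
#'
#' @param signal_image Numeric matrix.
#' @param nuclear_mask,cell_mask Logical matrices; the nucleus must lie
#'   inside the cell and the cytoplasmic remainder must be non-empty.
#' @param background Scalar background offset subtracted before the ratio.
#' @return Ratio (dimensionless).
#' @export
nuclear_cytoplasmic_ratio <- function(signal_image, nuclear_mask, cell_mask,
                                      background = 0) {
  stopifnot(is.matrix(signal_image))
  if (any(nuclear_mask & !cell_mask)) abort("`nuclear_mask` must lie inside `cell_mask`")
  cyto <- cell_mask & !nuclear_mask
  if (!any(nuclear_mask)) abort("empty nuclear mask")
  if (!any(cyto)) abort("empty cytoplasmic remainder")
  img <- signal_image - background
  mean(img[nuclear_mask]) / mean(img[cyto])
}
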