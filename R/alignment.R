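#' Fibril orientations from intensity gradients in image subregions
#'
#' Estimates the dominant fiber orientation in each subregion of a
#' reflection-style image from the structure tensor (sums of outer products
#' of the intensity gradient over the subregion). The fiber axis is
#' perpendicular to the dominant gradient direction. Subregions whose
#' coherence (normalized eigenvalue anisotropy of the structure tensor) falls
#' below `coherence_min` are dropped as featureless.
#'
#' Angles follow the package convention: degrees in `[0, 180)` measured
#' counter-clockwise from the +x (column) axis with y pointing up.
#'
#' @param image Numeric matrix (intensities, `>= 64 x 64`) or a
#'   `fiber_image`.
#' @param subregion_size Subregion side, pixels (`>= 8`). The default 8 with
#'   the default stride 16 gives a 30 x 30 = 900 measurement grid on a
#'   480 px image, the grid used for rose plots.
#' @param stride Spacing of the measurement grid, pixels (default
#'   `2 * subregion_size`). A stride larger than the subregion leaves gaps
#'   between windows, decorrelating neighbouring measurements (a fiber or the
#'   optical blur would otherwise straddle adjacent windows and couple them,
#'   which biases uniformity tests).
#' @param coherence_min Minimum coherence in `[0, 1]`; default 0.2.
#' @param presmooth_sigma Gaussian pre-smoothing of the image before
#'   differentiation, pixels (0 = none).
#' @return An `orientation_sample` tibble: `x, y` (subregion centers, px,
#'   y up from the bottom row), `angle` (degrees), `coherence`.
#' @export
subregion_orientations <- function(image, subregion_size = 8,
                                   stride = 2 * subregion_size,
                                   coherence_min = 0.2,
                                   presmooth_sigma = 1) {
  if (inherits(image, "fiber_image")) image <- image$image
  if (!is.matrix(image) || min(dim(image)) < 64) {
    abort("`image` must be a numeric matrix of at least 64 x 64 px")
  }
  if (subregion_size < 8) abort("`subregion_size` must be >= 8 px")
  if (presmooth_sigma > 0) image <- EBImage::gblur(image, sigma = presmooth_sigma)
  nr <- nrow(image); nc <- ncol(image)
  # central-difference gradients on the interior
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  gx[, 2:(nc - 1)] <- (image[, 3:nc] - image[, 1:(nc - 2)]) / 2
  # y points up = towards decreasing row index
  gy[2:(nr - 1), ] <- (image[1:(nr - 2), ] - image[3:nr, ]) / 2
  s <- subregion_size
  if (stride < s) abort("`stride` must be >= `subregion_size`")
  nbr <- (nr - s) %/% stride + 1L; nbc <- (nc - s) %/% stride + 1L
  if (nbr < 1 || nbc < 1) abort("`subregion_size` exceeds the image")
  # block id per pixel; pixels in the gaps between windows get NA
  pix_block <- function(n_px, nb) {
    off <- (seq_len(n_px) - 1L) %% stride
    blk <- (seq_len(n_px) - 1L) %/% stride
    ifelse(off < s & blk < nb, blk, NA_integer_)
  }
  block_r <- pix_block(nr, nbr)
  block_c <- pix_block(nc, nbc)
  bid <- outer(block_r, block_c, function(a, b) a + nbr * b) + 1L
  keep_px <- !is.na(bid)
  sum_by_block <- function(m) {
    out <- numeric(nbr * nbc)
    acc <- rowsum(as.vector(m)[keep_px], as.vector(bid)[keep_px])
    out[as.integer(rownames(acc))] <- acc[, 1]
    out
  }
  Jxx <- sum_by_block(gx^2)
  Jyy <- sum_by_block(gy^2)
  Jxy <- sum_by_block(gx * gy)
  tr <- Jxx + Jyy
  coh <- ifelse(tr > 0, sqrt((Jxx - Jyy)^2 + 4 * Jxy^2) / tr, 0)
  grad_angle <- rad2deg(0.5 * atan2(2 * Jxy, Jxx - Jyy))
  fiber_angle <- (grad_angle + 90) %% 180
  centers_r <- (seq_len(nbr) - 1) * stride + (s + 1) / 2   # block row centers
  centers_c <- (seq_len(nbc) - 1) * stride + (s + 1) / 2
  out <- tibble(
    x = rep(centers_c, each = nbr),
    y = nr - rep(centers_r, times = nbc),         # y up
    angle = fiber_angle,
    coherence = coh
  )
  dropped <- out$coherence < coherence_min | tr <= 0
  out <- out[!dropped, , drop = FALSE]
  if (nrow(out) == 0L) {
    warn("all subregions dropped (flat image or coherence below threshold)")
  }
  class(out) <- c("orientation_sample", class(out))
  out
}

sample_angles <- function(sample) {
  if (is.data.frame(sample)) sample$angle else as.numeric(sample)
}

#' Circular histogram of axial fiber orientations
#'
#' @param sample An `orientation_sample` (or numeric angles, degrees).
#' @param n_bins Number of bins over `[0, 180)`.
#' @param reference_angle Optional reference direction (e.g. the migration
#'   direction), degrees.
#' @return An `orientation_histogram` tibble: `bin_start, bin_end, bin_mid,
#'   count`; attributes `n`, `reference_angle`.
#' @export
orientation_histogram <- function(sample, n_bins = 18, reference_angle = NULL) {
  angles <- sample_angles(sample) %% 180
  if (length(angles) == 0L) abort("empty orientation sample")
  edges <- seq(0, 180, length.out = n_bins + 1)
  idx <- findInterval(angles, edges, rightmost.closed = FALSE)
  idx[idx > n_bins] <- n_bins
  counts <- tabulate(idx, nbins = n_bins)
  out <- tibble(
    bin_start = edges[-(n_bins + 1)], bin_end = edges[-1],
    bin_mid = (edges[-(n_bins + 1)] + edges[-1]) / 2,
    count = counts
  )
  attr(out, "n") <- length(angles)
  attr(out, "reference_angle") <- reference_angle
  class(out) <- c("orientation_histogram", class(out))
  out
}

#' Alignment statistics of an axial orientation sample
#'
#' Doubled-angle circular mean, alignment index `R` (resultant length of the
#' doubled angles: 0 = isotropic, 1 = perfectly aligned), Rayleigh test of
#' uniformity, and, when a reference direction is given, the angle difference
#' `delta_theta` of every fiber to that reference, folded into `[0, 90]`
#' degrees (0 = fiber parallel to the reference).
#'
#' @param sample An `orientation_sample` tibble or numeric angles (degrees).
#' @param reference_angle Optional reference orientation, degrees.
#' @return An `alignment_stats` object: list with `n`, `mean_angle`, `R`,
#'   `p_rayleigh`, and (with a reference) `delta_theta` plus
#'   `delta_theta_median`.
#' @export
alignment_stats <- function(sample, reference_angle = NULL) {
  angles <- sample_angles(sample)
  if (length(angles) == 0L) abort("empty orientation sample")
  res <- circular_mean(angles, axial = TRUE)
  ray <- rayleigh_test(angles, axial = TRUE)
  out <- list(n = res$n, mean_angle = res$mean, R = res$R,
              p_rayleigh = ray$p.value, reference_angle = reference_angle)
  if (!is.null(reference_angle)) {
    dt <- axial_difference(angles, reference_angle)
    out$delta_theta <- dt
    out$delta_theta_median <- median(dt)
  }
  structure(out, class = "alignment_stats")
}

#' @export
print.alignment_stats <- function(x, ...) {
  cat(sprintf("<alignment_stats> n = %d, mean = %.1f deg, R = %.3f, Rayleigh p = %.3g\n",
              x$n, x$mean_angle, x$R, x$p_rayleigh))
  if (!is.null(x$reference_angle)) {
    cat(sprintf("  delta-theta vs %.1f deg: median %.1f deg\n",
                x$reference_angle, x$delta_theta_median))
  }
  invisible(x)
}

#' Permutation contrast of alignment between two regions
#'
#' Compares the alignment index `R` between two orientation samples (e.g.
#' matrix adjacent to the invasive front vs far from the tissue) with a
#' label-shuffling permutation test on `R_near - R_far`. The two-sided
#' p-value uses the add-one convention.
#'
#' @param near_sample,far_sample Orientation samples (tibbles or angles,
#'   degrees).
#' @param n_perm Number of permutations.
#' @param seed Integer RNG seed for the permutations.
#' @return A `region_comparison` list: `R_near`, `R_far`, `diff`, `p_value`,
#'   `n_perm`.
#' @export
compare_regions <- function(near_sample, far_sample, n_perm = 10000, seed = 1L) {
  a <- sample_angles(near_sample); b <- sample_angles(far_sample)
  if (length(a) == 0L || length(b) == 0L) abort("both samples must be non-empty")
  n1 <- length(a)
  pool2 <- deg2rad(2 * c(a, b))
  cs <- cos(pool2); sn <- sin(pool2)
  Rgrp <- function(idx1) {
    c1 <- mean(cs[idx1]); s1 <- mean(sn[idx1])
    c2 <- mean(cs[-idx1]); s2 <- mean(sn[-idx1])
    sqrt(c1^2 + s1^2) - sqrt(c2^2 + s2^2)
  }
  obs <- Rgrp(seq_len(n1))
  perm <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(i) {
      Rgrp(sample.int(length(pool2), n1))
    }, numeric(1))
  })
  p <- (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
  structure(
    list(R_near = circular_mean(a, axial = TRUE)$R,
         R_far = circular_mean(b, axial = TRUE)$R,
         diff = obs, p_value = p, n_perm = n_perm),
    class = "region_comparison"
  )
}

#' @export
print.region_comparison <- function(x, ...) {
  cat(sprintf("<region_comparison> R_near = %.3f, R_far = %.3f, diff = %.3f, p = %.3g (%d perms)\n",
              x$R_near, x$R_far, x$diff, x$p_value, x$n_perm))
  invisible(x)
}
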