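#' Circular base-tissue mask
#'
#' @param size Image side, pixels.
#' @param radius Tissue radius, pixels.
#' @return Logical matrix; the tissue is centered in the image.
#' @export
disk_mask <- function(size = 96, radius = 20) {
  ctr <- (size + 1) / 2
  xc <- matrix(rep(seq_len(size), each = size), size) - ctr   # x = col
  yc <- ctr - matrix(rep(seq_len(size), size), size)          # y up
  sqrt(xc^2 + yc^2) <= radius
}

mask_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  c(x = mean(idx[, 2]), y_row = mean(idx[, 1]))
}

#' Synthesize a stack of binarized tissue masks with invading cohorts
#'
#' Emulates replicate microfabricated tissues of identical initial geometry,
#' each sprouting one or more migrating cohorts at angles drawn from a stated
#' distribution. Each mask is the union of the base shape and rectangular
#' protrusions extending radially outward at the drawn angles. True angles
#' are returned for validating directionality estimators.
#'
#' @param n_tissues Number of replicate masks.
#' @param base_shape Logical matrix: the common initial tissue geometry.
#' @param angle_dist Either `list(type = "uniform")` or
#'   `list(type = "vonmises", mean = <deg>, kappa = <conc>)`; directional
#'   angles in `[0, 360)`, 0 = east (+x), measured counter-clockwise.
#' @param n_cohorts Cohorts per tissue.
#' @param cohort_length,cohort_width Protrusion length/width, pixels.
#' @param seed Integer RNG seed.
#' @return A `mask_stack`: list with `masks` (list of logical matrices),
#'   `angles` (tibble `tissue, angle`), `base_shape`.
#' @export
synthesize_mask_stack <- function(n_tissues = 50,
                                  base_shape = disk_mask(),
                                  angle_dist = list(type = "uniform"),
                                  n_cohorts = 1L,
                                  cohort_length = 25, cohort_width = 9,
                                  seed = 1L) {
  stopifnot(is.matrix(base_shape))
  ctr <- c((ncol(base_shape) + 1) / 2, (nrow(base_shape) + 1) / 2)  # (x, row-ctr)
  # base radius along each direction: use max extent of base shape from center
  idx <- which(base_shape, arr.ind = TRUE)
  if (length(idx) == 0) abort("`base_shape` is empty")
  r0 <- max(sqrt((idx[, 2] - ctr[1])^2 + (idx[, 1] - ctr[2])^2))
  nr <- nrow(base_shape); nc <- ncol(base_shape)
  xg <- matrix(rep(seq_len(nc), each = nr), nr) - ctr[1]
  yg <- ctr[2] - matrix(rep(seq_len(nr), nc), nr)     # y up
  total <- n_tissues * n_cohorts
  ang <- withr::with_seed(as.integer(seed), {
    if (identical(angle_dist$type, "uniform")) {
      runif(total, 0, 360)
    } else if (identical(angle_dist$type, "vonmises")) {
      rad2deg(rvonmises(total, deg2rad(angle_dist$mean), angle_dist$kappa)) %% 360
    } else {
      abort("`angle_dist$type` must be 'uniform' or 'vonmises'")
    }
  })
  masks <- vector("list", n_tissues)
  for (i in seq_len(n_tissues)) {
    m <- base_shape
    for (j in seq_len(n_cohorts)) {
      th <- deg2rad(ang[(i - 1) * n_cohorts + j])
      # coordinates along (u) and across (v) the protrusion axis
      u <- xg * cos(th) + yg * sin(th)
      v <- -xg * sin(th) + yg * cos(th)
      m <- m | (u >= r0 - 2 & u <= r0 + cohort_length & abs(v) <= cohort_width / 2)
    }
    masks[[i]] <- m
  }
  structure(
    list(masks = masks,
         angles = tibble(tissue = rep(seq_len(n_tissues), each = n_cohorts),
                         angle = ang),
         base_shape = base_shape),
    class = "mask_stack"
  )
}

#' @export
print.mask_stack <- function(x, ...) {
  cat(sprintf("<mask_stack> %d masks of %d x %d px\n",
              length(x$masks), nrow(x$base_shape), ncol(x$base_shape)))
  invisible(x)
}
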