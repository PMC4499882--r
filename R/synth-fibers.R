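#' Specification of a synthetic fibrillar image
#'
#' Parameters of the generator that emulates confocal-reflection-style images
#' of collagen: straight anti-aliased fibril segments with axial orientations
#' drawn from a (doubled-angle) von Mises distribution, Gaussian optical blur
#' and additive detector noise. Defaults give a 480 px image whose 30 x 30
#' grid of 16 px subregions yields 900 orientation measurements; fibers are
#' shorter than a subregion so neighbouring subregions stay close to
#' statistically independent.
#'
#' @param n_fibers Number of fibril segments.
#' @param mean_angle Mean axial orientation, degrees in `[0, 180)`.
#' @param kappa Axial von Mises concentration; 0 = isotropic.
#' @param image_size Image side, pixels.
#' @param pixel_size Physical pixel size, um/px (metadata only).
#' @param fiber_length,fiber_width Segment length/width, pixels.
#' @param blur_sigma Gaussian blur SD, pixels.
#' @param noise_sigma Additive Gaussian noise SD, intensity units (image is
#'   normalized to peak 1 before noise).
#' @param seed Integer RNG seed.
#' @return A `fiber_field_spec` object.
#' @export
fiber_field_spec <- function(n_fibers = 1500, mean_angle = 90, kappa = 0,
                             image_size = 480, pixel_size = 0.25,
                             fiber_length = 8, fiber_width = 1.5,
                             blur_sigma = 1, noise_sigma = 0.02, seed = 1L) {
  if (kappa < 0) abort("`kappa` must be >= 0")
  if (mean_angle < 0 || mean_angle >= 180) abort("`mean_angle` must be in [0, 180)")
  if (image_size < 64) abort("`image_size` must be >= 64 px")
  structure(
    list(n_fibers = as.integer(n_fibers), mean_angle = mean_angle, kappa = kappa,
         image_size = as.integer(image_size), pixel_size = pixel_size,
         fiber_length = fiber_length, fiber_width = fiber_width,
         blur_sigma = blur_sigma, noise_sigma = noise_sigma,
         seed = as.integer(seed)),
    class = "fiber_field_spec"
  )
}

# Accumulate weights at fractional (x, y) positions into an image matrix by
# bilinear splatting. x = column, y measured upward from the bottom row.
splat_bilinear <- function(img, x, y, w) {
  n <- nrow(img)
  # convert y-up to row index (fractional): row = n - y
  r <- n - y
  c0 <- floor(x); r0 <- floor(r)
  fx <- x - c0; fr <- r - r0
  cs <- c(c0, c0 + 1, c0, c0 + 1)
  rs <- c(r0, r0, r0 + 1, r0 + 1)
  ws <- c(w * (1 - fx) * (1 - fr), w * fx * (1 - fr),
          w * (1 - fx) * fr, w * fx * fr)
  keep <- cs >= 1 & cs <= ncol(img) & rs >= 1 & rs <= n & ws > 0
  idx <- (cs[keep] - 1L) * n + rs[keep]
  acc <- rowsum(ws[keep], idx)
  ii <- as.integer(rownames(acc))
  img[ii] <- img[ii] + acc[, 1]
  img
}

#' Render a synthetic fibrillar image
#'
#' Draws `n_fibers` anti-aliased line segments at axial angles sampled from
#' the doubled-angle von Mises distribution of the spec, applies Gaussian
#' blur, peak-normalizes, and adds Gaussian noise (clipped at 0). The sampled
#' true angles are returned alongside the image so orientation estimators can
#' be validated against ground truth.
#'
#' @param spec A [fiber_field_spec()].
#' @return A `fiber_image`: list with `image` (matrix in `[0, ~1]`,
#'   rows = image y from top), `angles` (true axial angles, degrees),
#'   `spec`.
#' @export
render_fiber_image <- function(spec) {
  stopifnot(inherits(spec, "fiber_field_spec"))
  s <- spec$image_size
  res <- withr::with_seed(spec$seed, {
    img <- matrix(0, s, s)
    angles <- numeric(0)
    if (spec$n_fibers > 0) {
      angles <- sample_axial_angles(spec$n_fibers, spec$mean_angle, spec$kappa)
      cx <- runif(spec$n_fibers, 1, s)
      cy <- runif(spec$n_fibers, 1, s)
      th <- deg2rad(angles)
      dx <- cos(th); dy <- sin(th)
      step <- 0.4
      tpar <- seq(-spec$fiber_length / 2, spec$fiber_length / 2, by = step)
      wid <- seq(-spec$fiber_width / 2, spec$fiber_width / 2, by = 0.5)
      # all sample points of all fibers, vectorized over fibers x t x width
      for (wo in wid) {
        px <- outer(cx - wo * dy, rep(1, length(tpar))) + outer(dx, tpar)
        py <- outer(cy + wo * dx, rep(1, length(tpar))) + outer(dy, tpar)
        img <- splat_bilinear(img, as.vector(px), as.vector(py),
                              rep(step, length(px)))
      }
    }
    if (spec$blur_sigma > 0) {
      img <- EBImage::gblur(img, sigma = spec$blur_sigma)
    }
    if (max(img) > 0) img <- img / max(img)
    if (spec$noise_sigma > 0) {
      img <- img + matrix(rnorm(s * s, sd = spec$noise_sigma), s, s)
      img[img < 0] <- 0
    }
    list(image = img, angles = angles)
  })
  structure(list(image = res$image, angles = res$angles, spec = spec),
            class = "fiber_image")
}

#' @export
print.fiber_image <- function(x, ...) {
  cat(sprintf("<fiber_image> %d x %d px, %d fibers, kappa = %g, mean = %g deg\n",
              nrow(x$image), ncol(x$image), length(x$angles),
              x$spec$kappa, x$spec$mean_angle))
  invisible(x)
}
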