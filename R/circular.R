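# Circular statistics helpers. Fiber orientations are axial data (defined
# modulo 180 degrees) and are analysed on doubled angles; invasion directions
# are ordinary circular data on [0, 360).

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler. `kappa = 0` reduces to the circular uniform
#' distribution.
#'
#' @param n Number of draws.
#' @param mu Mean direction, radians.
#' @param kappa Concentration, `>= 0`.
#' @return Radians in `[0, 2*pi)`. RNG state is taken from the caller.
#' @export
rvonmises <- function(n, mu = 0, kappa = 0) {
  if (kappa < 0) abort("`kappa` must be >= 0")
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-10) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    k <- sum(ok)
    if (k > 0) {
      theta <- sign(u3[ok] - 0.5) * acos(f[ok])
      out[(got + 1L):(got + k)] <- theta
      got <- got + k
    }
  }
  (mu + out) %% (2 * pi)
}

#' Sample axial fiber angles
#'
#' Axial von Mises draw via the doubled-angle device: sample
#' `phi ~ vonMises(2 * mean_angle, kappa)` and return `phi / 2` folded into
#' `[0, 180)` degrees. `kappa = 0` gives isotropic orientations.
#'
#' @param n Number of fibers.
#' @param mean_angle Mean orientation, degrees in `[0, 180)`.
#' @param kappa Axial concentration (on the doubled angle), `>= 0`.
#' @return Degrees in `[0, 180)`.
#' @export
sample_axial_angles <- function(n, mean_angle = 90, kappa = 0) {
  if (mean_angle < 0 || mean_angle >= 180) abort("`mean_angle` must be in [0, 180)")
  phi <- rvonmises(n, mu = deg2rad(2 * mean_angle), kappa = kappa)
  (rad2deg(phi) / 2) %% 180
}

# Resultant length and mean of a set of angles given in degrees with the
# stated period (360 for directions, 180 for axial data via doubling).
circular_resultant <- function(angles_deg, period = 360) {
  fold <- 360 / period
  th <- deg2rad(angles_deg * fold)
  C <- mean(cos(th)); S <- mean(sin(th))
  R <- sqrt(C^2 + S^2)
  mean_angle <- (rad2deg(atan2(S, C)) / fold) %% period
  list(R = R, mean = mean_angle, n = length(angles_deg))
}

#' Circular mean and alignment index
#'
#' @param angles_deg Angles in degrees.
#' @param axial If `TRUE`, treat angles as orientations modulo 180 degrees
#'   (computed on doubled angles).
#' @return List with `mean` (degrees), `R` (resultant length in `[0, 1]`) and `n`.
#' @export
circular_mean <- function(angles_deg, axial = FALSE) {
  circular_resultant(angles_deg, period = if (axial) 180 else 360)
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null of a uniform angular distribution against unimodal
#' concentration, using the standard large-sample approximation with the
#' second-order correction. For axial data the test is applied to doubled
#' angles.
#'
#' @inheritParams circular_mean
#' @return `htest`-like list with `statistic` (Z = n R^2), `p.value`, `R`,
#'   `mean`, `n`.
#' @export
rayleigh_test <- function(angles_deg, axial = FALSE) {
  res <- circular_mean(angles_deg, axial = axial)
  n <- res$n
  if (n < 2L) abort("need at least two angles")
  Z <- n * res$R^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - (n * res$R)^2)) - (1 + 2 * n))
  p <- min(max(p, 0), 1)
  structure(
    list(statistic = c(Z = Z), p.value = p, R = res$R, mean = res$mean, n = n,
         method = if (axial) "Rayleigh test (axial, doubled angles)" else "Rayleigh test",
         data.name = deparse(substitute(angles_deg))),
    class = "htest"
  )
}

#' Angle differences
#'
#' `axial_difference()` folds the difference between two orientations into
#' `[0, 90]` degrees (0 = parallel, 90 = perpendicular), the delta-theta used
#' to compare fibril orientation with the direction of an extending branch.
#' `directional_difference()` is the analogous `[0, 180]` difference for
#' directions.
#'
#' @param a,b Angles, degrees.
#' @return Degrees.
#' @export
axial_difference <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' @rdname axial_difference
#' @export
directional_difference <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}
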