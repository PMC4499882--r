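#' Displacement field of a tensile spherical cavity
#'
#' Closed-form (Lame) solution for a spherical interface of radius `a` in an
#' infinite isotropic gel carrying a uniform normal traction of magnitude `p`.
#' With the tensile convention used throughout the package, `p > 0` means the
#' tissue pulls the surrounding matrix inward (beads move toward the tissue),
#' and the displacement is
#' \deqn{u(r) = - \frac{p a^3}{4 \mu r^2} \hat r,}
#' purely radial and decaying as \eqn{r^{-2}}. This is the forward oracle used
#' to validate interpolation, strain, and the finite element solve.
#'
#' @param points Query points (n x 3 matrix or data frame with `x, y, z`, um),
#'   all at radius `>= a` from `center`.
#' @param material An [elastic_material()].
#' @param a Cavity (tissue) radius, um.
#' @param p Interface traction magnitude, Pa; `p > 0` is tensile (inward pull).
#' @param center Cavity center, um.
#' @return Tibble with `x, y, z, ux, uy, uz` (um).
#' @examples
#' m <- elastic_material(500, 0.2)
#' u <- cavity_displacement_field(c(100, 0, 0), m, a = 50, p = 100)
#' sqrt(sum(u[, 4:6]^2))  # 1.5 um
#' @export
cavity_displacement_field <- function(points, material, a, p, center = c(0, 0, 0)) {
  material <- as_material(material)
  if (a <= 0) abort("cavity radius `a` must be positive")
  pts <- as_point_matrix(points)
  q <- sweep(pts, 2, center)
  r <- sqrt(rowSums(q^2))
  if (any(r < a * (1 - 1e-9))) {
    abort("all `points` must lie outside the cavity (r >= a)")
  }
  amp <- -p * a^3 / (4 * material$mu * r^2)  # signed radial displacement
  vec <- q * (amp / r)
  if (p == 0) vec <- matrix(0, nrow(pts), 3)
  vector_field_tibble(pts, vec)
}

# Radial stress of the cavity solution, sigma_rr(r) = p a^3 / r^3 (tension > 0).
cavity_radial_stress <- function(r, a, p) p * a^3 / r^3

#' Kelvin point-force displacement field
#'
#' Displacement in an infinite isotropic medium due to a concentrated force
#' `F` applied at `location`:
#' \deqn{u_i = \frac{F_j}{16 \pi \mu (1 - \nu) r}
#'        \left[(3 - 4\nu)\,\delta_{ij} + \hat r_i \hat r_j\right].}
#' The magnitude decays as \eqn{r^{-1}} and the field is axisymmetric about
#' the force axis. Used to emulate localized pulling at the invasive front of
#' a migrating cohort.
#'
#' @param points Query points (um); must not coincide with `location`.
#' @param material An [elastic_material()].
#' @param force Length-3 force vector, Pa um^2.
#' @param location Length-3 application point, um.
#' @return Tibble with `x, y, z, ux, uy, uz` (um).
#' @export
kelvin_displacement_field <- function(points, material, force,
                                      location = c(0, 0, 0)) {
  material <- as_material(material)
  force <- as.numeric(force)
  if (length(force) != 3L || !all(is.finite(force))) abort("`force` must be length 3")
  pts <- as_point_matrix(points)
  q <- sweep(pts, 2, location)
  r <- sqrt(rowSums(q^2))
  if (any(r < 1e-9)) abort("`points` must not coincide with the force location")
  pref <- 1 / (16 * pi * material$mu * (1 - material$nu) * r)
  k <- 3 - 4 * material$nu
  rhat <- q / r
  rdotF <- as.vector(rhat %*% force)
  vec <- pref * (k * matrix(force, nrow(pts), 3, byrow = TRUE) + rhat * rdotF)
  if (all(force == 0)) vec <- matrix(0, nrow(pts), 3)
  vector_field_tibble(pts, vec)
}
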