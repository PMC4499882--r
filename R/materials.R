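#' Isotropic linear-elastic material
#'
#' Bundles the engineering constants of an isotropic Hookean solid with the
#' Lame parameters used in the constitutive law `T = 2 mu eps + lambda tr(eps) I`.
#' Collagen gels are modelled this way as a first approximation: the solve is
#' used for the spatial pattern and directionality of traction rather than
#' absolute magnitude, so the (hard to pin down) gel modulus mostly sets the
#' overall scale.
#'
#' @param E Young's modulus in Pa. The default 500 Pa is a plausible value for
#'   a dense collagen gel; it is a configurable placeholder, not a measured
#'   constant.
#' @param nu Poisson ratio, in `[0, 0.5)`. Default 0.2.
#' @return An object of class `elastic_material`: a list with fields `E`,
#'   `nu`, `mu` (shear modulus) and `lambda`.
#' @examples
#' m <- elastic_material(E = 500, nu = 0.2)
#' m$mu      # 208.33 Pa
#' m$lambda  # 138.89 Pa
#' @export
elastic_material <- function(E = 500, nu = 0.2) {
  if (!is.numeric(E) || length(E) != 1L || !is.finite(E) || E <= 0) {
    abort("`E` must be a single positive number (Pa)")
  }
  if (!is.numeric(nu) || length(nu) != 1L || !is.finite(nu) || nu < 0 || nu >= 0.5) {
    abort("`nu` must lie in [0, 0.5); the incompressible limit is unsupported")
  }
  lame <- lame_parameters(E, nu)
  structure(
    list(E = E, nu = nu, mu = lame[["mu"]], lambda = lame[["lambda"]]),
    class = "elastic_material"
  )
}

#' Lame parameters from engineering constants
#'
#' @inheritParams elastic_material
#' @return Named numeric vector with `mu = E / (2 (1 + nu))` and
#'   `lambda = E nu / ((1 + nu) (1 - 2 nu))`, both in Pa.
#' @export
lame_parameters <- function(E, nu) {
  if (nu >= 0.5) abort("`nu` must be < 0.5")
  c(mu = E / (2 * (1 + nu)), lambda = E * nu / ((1 + nu) * (1 - 2 * nu)))
}

#' @export
print.elastic_material <- function(x, ...) {
  cat(sprintf(
    "<elastic_material> E = %g Pa, nu = %g (mu = %.4g Pa, lambda = %.4g Pa)\n",
    x$E, x$nu, x$mu, x$lambda
  ))
  invisible(x)
}

as_material <- function(material) {
  if (inherits(material, "elastic_material")) return(material)
  if (is.list(material) && all(c("E", "nu") %in% names(material))) {
    return(elastic_material(material$E, material$nu))
  }
  abort("`material` must be an elastic_material (see `elastic_material()`)")
}

# 6x6 isotropic stiffness acting on engineering strain
# (exx, eyy, ezz, gxy, gyz, gxz).
stiffness_matrix <- function(material) {
  mu <- material$mu
  la <- material$lambda
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- la
  diag(D)[1:3] <- la + 2 * mu
  diag(D)[4:6] <- mu
  D
}
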