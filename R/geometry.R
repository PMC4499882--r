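#' Gel domain shapes
#'
#' Axis-aligned box and z-aligned cylinder domains in micrometres, used both
#' for seeding fiducial beads and as the outer boundary of the meshed gel.
#' The default cylinder (2000 um height and diameter) mirrors the
#' computational gel domain enclosing a microfabricated tissue.
#'
#' @param lower,upper Numeric length-3 corners of the box (um).
#' @param radius,height Cylinder radius and height (um).
#' @param center Numeric length-3 center.
#' @return A `gel_domain` object.
#' @export
gel_box <- function(lower = c(-100, -100, -100), upper = c(100, 100, 100)) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != 3L || length(upper) != 3L) abort("corners must be length 3")
  if (any(upper <= lower)) abort("`upper` must exceed `lower` in every coordinate")
  structure(list(type = "box", lower = lower, upper = upper), class = "gel_domain")
}

#' @rdname gel_box
#' @export
gel_cylinder <- function(radius = 1000, height = 2000, center = c(0, 0, 0)) {
  if (radius <= 0 || height <= 0) abort("cylinder radius and height must be positive")
  structure(
    list(type = "cylinder", radius = radius, height = height,
         center = as.numeric(center)),
    class = "gel_domain"
  )
}

#' @export
print.gel_domain <- function(x, ...) {
  if (x$type == "box") {
    cat(sprintf("<gel_domain> box [%s] to [%s] um\n",
                paste(x$lower, collapse = ", "), paste(x$upper, collapse = ", ")))
  } else {
    cat(sprintf("<gel_domain> cylinder r = %g um, h = %g um at (%s)\n",
                x$radius, x$height, paste(x$center, collapse = ", ")))
  }
  invisible(x)
}

#' Domain volume in cubic micrometres
#' @param domain A `gel_domain`.
#' @return Volume (um^3).
#' @export
domain_volume <- function(domain) {
  switch(domain$type,
    box = prod(domain$upper - domain$lower),
    cylinder = pi * domain$radius^2 * domain$height,
    abort("unknown domain type")
  )
}

#' Test whether points lie inside a domain
#' @param domain A `gel_domain`.
#' @param points n x 3 matrix or data frame with x, y, z (um).
#' @return Logical vector of length n.
#' @export
domain_contains <- function(domain, points) {
  p <- as_point_matrix(points)
  if (domain$type == "box") {
    lo <- domain$lower; hi <- domain$upper
    (p[, 1] >= lo[1] & p[, 1] <= hi[1] &
     p[, 2] >= lo[2] & p[, 2] <= hi[2] &
     p[, 3] >= lo[3] & p[, 3] <= hi[3])
  } else {
    q <- sweep(p, 2, domain$center)
    sqrt(q[, 1]^2 + q[, 2]^2) <= domain$radius & abs(q[, 3]) <= domain$height / 2
  }
}

# Uniform points in a domain; assumes RNG state managed by the caller.
sample_points_in_domain <- function(domain, n) {
  if (n == 0L) return(matrix(numeric(0), 0, 3))
  if (domain$type == "box") {
    lo <- domain$lower; hi <- domain$upper
    cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]), runif(n, lo[3], hi[3]))
  } else {
    r <- domain$radius * sqrt(runif(n))
    th <- runif(n, 0, 2 * pi)
    z <- runif(n, -domain$height / 2, domain$height / 2)
    sweep(cbind(r * cos(th), r * sin(th), z), 2, domain$center, `+`)
  }
}

# Distance from `origin` along unit directions `dirs` (n x 3) to the domain
# boundary; origin must be inside. Used to extrude radial gel meshes.
ray_exit_distance <- function(domain, origin, dirs) {
  n <- nrow(dirs)
  if (domain$type == "cylinder") {
    o <- origin - domain$center
    # lateral wall: |o_xy + t d_xy| = R
    dx <- dirs[, 1]; dy <- dirs[, 2]; dz <- dirs[, 3]
    a <- dx^2 + dy^2
    b <- 2 * (o[1] * dx + o[2] * dy)
    cc <- o[1]^2 + o[2]^2 - domain$radius^2
    t_side <- ifelse(a > 1e-14, (-b + sqrt(pmax(b^2 - 4 * a * cc, 0))) / (2 * a), Inf)
    t_cap <- ifelse(abs(dz) > 1e-14,
                    (sign(dz) * domain$height / 2 - o[3]) / dz, Inf)
    pmin(t_side, t_cap)
  } else {
    t <- rep(Inf, n)
    for (ax in 1:3) {
      d <- dirs[, ax]
      far <- ifelse(d > 0, domain$upper[ax] - origin[ax], domain$lower[ax] - origin[ax])
      ti <- ifelse(abs(d) > 1e-14, far / d, Inf)
      t <- pmin(t, ti)
    }
    t
  }
}
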