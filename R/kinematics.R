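#' Displacement field from bead tracks
#'
#' Subtracts each bead's position at the reference time (the force-free
#' configuration, experimentally the post-lysis state) from its position at
#' every other time. The field is sampled at the reference positions.
#'
#' @param tracks Bead-track tibble with columns `bead_id, t, x, y, z`
#'   (see [read_bead_tracks()]).
#' @param reference_time Time of the force-free reference, hours.
#' @param time Optional single time to extract; default all non-reference
#'   times.
#' @param tol Time-matching tolerance, hours.
#' @return A `displacement_field` tibble with columns
#'   `bead_id, t, x, y, z, ux, uy, uz` where `x, y, z` are reference
#'   positions. Beads missing the reference time are dropped with a warning.
#' @export
displacements_from_tracks <- function(tracks, reference_time, time = NULL,
                                      tol = 1e-6) {
  required <- c("bead_id", "t", "x", "y", "z")
  if (!all(required %in% names(tracks))) {
    abort("`tracks` must have columns bead_id, t, x, y, z")
  }
  ref <- tracks %>%
    filter(abs(.data$t - reference_time) <= tol) %>%
    distinct(.data$bead_id, .keep_all = TRUE) %>%
    select("bead_id", x0 = "x", y0 = "y", z0 = "z")
  missing <- setdiff(unique(tracks$bead_id), ref$bead_id)
  if (length(missing) == length(unique(tracks$bead_id))) {
    abort("no track contains the reference time")
  }
  if (length(missing) > 0) {
    warn(sprintf("%d track(s) missing the reference time were excluded",
                 length(missing)))
  }
  out <- tracks %>%
    filter(abs(.data$t - reference_time) > tol) %>%
    dplyr::inner_join(ref, by = "bead_id") %>%
    mutate(ux = .data$x - .data$x0, uy = .data$y - .data$y0,
           uz = .data$z - .data$z0) %>%
    select("bead_id", "t", x = "x0", y = "y0", z = "z0", "ux", "uy", "uz")
  if (!is.null(time)) {
    out <- filter(out, abs(.data$t - time) <= tol)
  }
  attr(out, "reference_time") <- reference_time
  class(out) <- c("displacement_field", class(out))
  out
}

single_time_field <- function(field) {
  if ("t" %in% names(field) && length(unique(field$t)) > 1L) {
    abort("field spans multiple times; select one with `time =` or filter(t == ...)")
  }
  field
}

# Estimate the mean nearest-neighbour spacing of a Poisson cloud from its
# bounding-box density: E[NN] ~= 0.554 * density^(-1/3).
estimate_spacing <- function(pts) {
  n <- nrow(pts)
  vol <- prod(apply(pts, 2, function(v) diff(range(v))))
  if (vol <= 0 || n < 2) return(1)
  0.554 * (vol / n)^(1 / 3)
}

wendland_c2 <- function(r, s) {
  q <- pmin(r / s, 1)
  (1 - q)^4 * (4 * q + 1)
}

#' Scattered-data interpolator for a displacement field
#'
#' Fits a radial-basis-function interpolant per displacement component to the
#' sampled bead displacements, the continuous stand-in for the measured
#' field. Methods: `"gaussian"` (default; dense Gaussian kernel with a small
#' ridge, `length_scale` defaulting to twice the mean nearest-neighbour bead
#' spacing), `"wendland"` (compactly supported C2 kernel, sparse, for large
#' bead clouds) and `"polyharmonic"` (`phi(r) = r` plus an affine tail, which
#' reproduces affine fields exactly).
#'
#' @param field A single-time `displacement_field` (columns `x, y, z, ux, uy,
#'   uz`).
#' @param method Kernel, see above.
#' @param length_scale Kernel length scale / support radius, um. Defaults to
#'   `2 *` (Gaussian) or `3 *` (Wendland) the estimated bead spacing.
#' @param ridge Diagonal regularization added to the kernel matrix (times its
#'   diagonal scale); stabilizes noisy data.
#' @return A `displacement_interpolator` with a [predict()] method.
#' @export
displacement_interpolator <- function(field,
                                      method = c("gaussian", "wendland",
                                                 "polyharmonic"),
                                      length_scale = NULL, ridge = 1e-8) {
  method <- match.arg(method)
  field <- single_time_field(field)
  pts <- as_point_matrix(field)
  U <- cbind(field$ux, field$uy, field$uz)
  if (!all(is.finite(U))) abort("displacement vectors must be finite")
  n <- nrow(pts)
  if (n < 4L) abort("need at least 4 sample points for 3D interpolation")
  if (qr(sweep(pts, 2, colMeans(pts)))$rank < 3L) {
    abort("sample points are coplanar; 3D interpolation needs non-coplanar data")
  }
  spacing <- estimate_spacing(pts)
  if (is.null(length_scale)) {
    length_scale <- if (method == "wendland") 3 * spacing else 2 * spacing
  }
  obj <- list(method = method, points = pts, length_scale = length_scale,
              ridge = ridge, n = n)
  if (method == "polyharmonic") {
    D <- as.matrix(stats::dist(pts))
    P <- cbind(1, pts)
    K <- rbind(cbind(D + ridge * diag(n), P),
               cbind(t(P), matrix(0, 4, 4)))
    rhs <- rbind(U, matrix(0, 4, 3))
    W <- solve(K, rhs)
    obj$weights <- W[seq_len(n), , drop = FALSE]
    obj$poly <- W[n + 1:4, , drop = FALSE]
  } else if (method == "gaussian") {
    D2 <- as.matrix(stats::dist(pts))^2
    K <- exp(-D2 / (2 * length_scale^2))
    diag(K) <- diag(K) + ridge
    obj$weights <- solve(K, U)
  } else {
    K <- sparse_kernel_matrix(pts, pts, length_scale)
    K <- K + Matrix::Diagonal(n, ridge)
    obj$weights <- as.matrix(Matrix::solve(K, U))
  }
  class(obj) <- "displacement_interpolator"
  obj
}

# Sparse Wendland kernel between point sets (dense distance computed
# block-wise, thresholded at the support radius).
sparse_kernel_matrix <- function(A, B, s, block = 2000L) {
  n <- nrow(A)
  trip_i <- list(); trip_j <- list(); trip_x <- list(); k <- 0L
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    D <- sqrt(pmax(outer(rowSums(A[rows, , drop = FALSE]^2), rowSums(B^2), `+`) -
                     2 * A[rows, , drop = FALSE] %*% t(B), 0))
    hit <- which(D < s, arr.ind = TRUE)
    k <- k + 1L
    trip_i[[k]] <- rows[hit[, 1]]
    trip_j[[k]] <- hit[, 2]
    trip_x[[k]] <- wendland_c2(D[hit], s)
  }
  Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                       x = unlist(trip_x), dims = c(n, nrow(B)))
}

#' Evaluate a displacement interpolator
#'
#' @param object A [displacement_interpolator()].
#' @param points Query points (um).
#' @param warn_extrapolation Warn when a query lies farther than the
#'   interpolator's length scale from every sample point.
#' @param ... Unused.
#' @return Tibble `x, y, z, ux, uy, uz, extrapolated`.
#' @export
predict.displacement_interpolator <- function(object, points,
                                              warn_extrapolation = TRUE, ...) {
  q <- as_point_matrix(points)
  U <- interp_eval(object, q)
  # distance to nearest sample, block-wise
  nd <- rep(Inf, nrow(q))
  for (start in seq(1L, nrow(q), by = 2000L)) {
    rows <- start:min(start + 1999L, nrow(q))
    D2 <- outer(rowSums(q[rows, , drop = FALSE]^2), rowSums(object$points^2), `+`) -
      2 * q[rows, , drop = FALSE] %*% t(object$points)
    nd[rows] <- sqrt(pmax(apply(D2, 1, min), 0))
  }
  extrap <- nd > object$length_scale
  if (warn_extrapolation && any(extrap)) {
    warn(sprintf("%d query point(s) lie beyond the interpolation length scale (extrapolation)",
                 sum(extrap)))
  }
  out <- vector_field_tibble(q, U)
  out$extrapolated <- extrap
  out
}

interp_eval <- function(object, q) {
  out <- matrix(0, nrow(q), 3)
  for (start in seq(1L, nrow(q), by = 2000L)) {
    rows <- start:min(start + 1999L, nrow(q))
    qq <- q[rows, , drop = FALSE]
    if (object$method == "polyharmonic") {
      D <- sqrt(pmax(outer(rowSums(qq^2), rowSums(object$points^2), `+`) -
                       2 * qq %*% t(object$points), 0))
      out[rows, ] <- D %*% object$weights + cbind(1, qq) %*% object$poly
    } else if (object$method == "gaussian") {
      D2 <- pmax(outer(rowSums(qq^2), rowSums(object$points^2), `+`) -
                   2 * qq %*% t(object$points), 0)
      out[rows, ] <- exp(-D2 / (2 * object$length_scale^2)) %*% object$weights
    } else {
      K <- sparse_kernel_matrix(qq, object$points, object$length_scale)
      out[rows, ] <- as.matrix(K %*% object$weights)
    }
  }
  out
}

# Plain function interface used by the FEM boundary conditions.
interpolator_function <- function(object) {
  force(object)
  function(points) interp_eval(object, as_point_matrix(points))
}

#' Interpolate a displacement field at query points
#'
#' Convenience wrapper: fit a [displacement_interpolator()] and evaluate it.
#'
#' @inheritParams displacement_interpolator
#' @param points Query points (um).
#' @param ... Passed to [displacement_interpolator()].
#' @return Tibble `x, y, z, ux, uy, uz, extrapolated`.
#' @export
interpolate_displacement <- function(field, points, ...) {
  predict(displacement_interpolator(field, ...), points)
}

#' Displacement gradient and deformation gradient at a point
#'
#' Differentiates the interpolated displacement field by central differences
#' with step `h` (default 1 um), giving `grad_u[i, j] = d u_i / d x_j`, the
#' deformation gradient `F = I + grad_u`, and `det(F)` (flagged when
#' non-positive, i.e. unphysical local inversion).
#'
#' @param interp A [displacement_interpolator()] (or any
#'   `function(points) -> n x 3 matrix`).
#' @param point Length-3 evaluation point, um.
#' @param h Central-difference step, um; must be positive.
#' @return A `deformation_gradient`: list with `point`, `grad_u`, `F`,
#'   `J = det(F)`, `physical = (J > 0)`.
#' @export
displacement_gradient <- function(interp, point, h = 1) {
  if (h <= 0) abort("`h` must be positive")
  f <- if (inherits(interp, "displacement_interpolator")) {
    interpolator_function(interp)
  } else interp
  point <- as.numeric(point)
  offsets <- rbind(diag(3) * h, -diag(3) * h)
  q <- sweep(offsets, 2, point, `+`)
  U <- f(q)
  grad_u <- t((U[1:3, , drop = FALSE] - U[4:6, , drop = FALSE]) / (2 * h))
  dimnames(grad_u) <- NULL
  Fm <- diag(3) + grad_u
  J <- det(Fm)
  structure(list(point = point, grad_u = grad_u, F = Fm, J = J,
                 physical = J > 0),
            class = "deformation_gradient")
}

as_grad_u <- function(x) {
  if (inherits(x, "deformation_gradient")) return(x$grad_u)
  x <- as.matrix(x)
  if (!all(dim(x) == c(3, 3))) abort("`grad_u` must be 3 x 3")
  if (!all(is.finite(x))) abort("`grad_u` must be finite")
  x
}

#' Finite and infinitesimal strain tensors
#'
#' `green_lagrange()` returns the finite-strain (Green-Lagrange) tensor
#' `E = (grad_u + grad_u^T + grad_u^T grad_u) / 2`, which vanishes for any
#' rigid-body motion. `small_strain()` returns the infinitesimal strain
#' `eps = (grad_u + grad_u^T) / 2`, the measure entering Hooke's law and the
#' elastic solve. Both are reported because finite-strain kinematics and
#' linear elasticity are deliberately mixed in this pipeline (see the
#' methods vignette).
#'
#' @param grad_u 3 x 3 displacement gradient, or a [displacement_gradient()]
#'   result.
#' @return Symmetric 3 x 3 matrix (dimensionless).
#' @export
green_lagrange <- function(grad_u) {
  g <- as_grad_u(grad_u)
  E <- (g + t(g) + t(g) %*% g) / 2
  (E + t(E)) / 2
}

#' @rdname green_lagrange
#' @export
small_strain <- function(grad_u) {
  g <- as_grad_u(grad_u)
  (g + t(g)) / 2
}

#' Strain components over a set of query points
#'
#' Tidy per-point strain table: differentiates the interpolant at each point
#' and reports both strain measures componentwise.
#'
#' @inheritParams displacement_gradient
#' @param points n x 3 matrix or data frame of query points (um).
#' @return Tibble with point coordinates, `J`, and columns
#'   `E_<ij>` (Green-Lagrange) and `eps_<ij>` (small strain).
#' @export
strain_table <- function(interp, points, h = 1) {
  pts <- as_point_matrix(points)
  rows <- purrr::map(seq_len(nrow(pts)), function(i) {
    dg <- displacement_gradient(interp, pts[i, ], h = h)
    E <- green_lagrange(dg); e <- small_strain(dg)
    tibble(
      x = pts[i, 1], y = pts[i, 2], z = pts[i, 3], J = dg$J,
      E_xx = E[1, 1], E_yy = E[2, 2], E_zz = E[3, 3],
      E_xy = E[1, 2], E_yz = E[2, 3], E_xz = E[1, 3],
      eps_xx = e[1, 1], eps_yy = e[2, 2], eps_zz = e[3, 3],
      eps_xy = e[1, 2], eps_yz = e[2, 3], eps_xz = e[1, 3]
    )
  })
  bind_rows(rows)
}
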