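# Linear-elastic finite elements on tetrahedra (P1 and P2, affine geometry).
# Engineering-strain ordering (exx, eyy, ezz, gxy, gyz, gxz) throughout.

tet_quadrature <- function(order) {
  if (order == 2L) {
    a <- 0.5854101966249685; b <- 0.1381966011250105
    list(bary = rbind(c(a, b, b, b), c(b, a, b, b), c(b, b, a, b), c(b, b, b, a)),
         w = rep(0.25, 4))
  } else {
    list(bary = matrix(0.25, 1, 4), w = 1)
  }
}

# Shape-function derivatives with respect to the reference (natural)
# coordinates xi = (L2, L3, L4) at one barycentric point. Elements are
# isoparametric: curved quadratic tets follow their midside nodes.
ref_shape_derivs <- function(L, order) {
  if (order == 1L) {
    dNdL <- diag(4)
  } else {
    dNdL <- matrix(0, 10, 4)
    for (i in 1:4) dNdL[i, i] <- 4 * L[i] - 1
    edges <- rbind(c(1, 2), c(2, 3), c(3, 1), c(1, 4), c(2, 4), c(3, 4))
    for (m in 1:6) {
      i <- edges[m, 1]; j <- edges[m, 2]
      dNdL[4 + m, i] <- 4 * L[j]
      dNdL[4 + m, j] <- 4 * L[i]
    }
  }
  dNdL[, 2:4, drop = FALSE] - dNdL[, 1]
}

# Physical shape-function gradients (nn x 3) and Jacobian determinant at one
# quadrature point of one element with node coordinates X (nn x 3).
iso_gradients <- function(X, dNdXi) {
  J <- crossprod(X, dNdXi)            # 3 x 3, J[k, m] = dx_k / dxi_m
  detJ <- det(J)
  list(G = dNdXi %*% solve(J), detJ = detJ)
}

strain_displacement_matrix <- function(G) {
  nn <- nrow(G)
  B <- matrix(0, 6, 3 * nn)
  ix <- 3 * seq_len(nn) - 2
  B[1, ix] <- G[, 1]
  B[2, ix + 1] <- G[, 2]
  B[3, ix + 2] <- G[, 3]
  B[4, ix] <- G[, 2]; B[4, ix + 1] <- G[, 1]
  B[5, ix + 1] <- G[, 3]; B[5, ix + 2] <- G[, 2]
  B[6, ix] <- G[, 3]; B[6, ix + 2] <- G[, 1]
  B
}

assemble_stiffness <- function(mesh, material) {
  D <- stiffness_matrix(material)
  els <- mesh$elements
  ne <- nrow(els)
  nn <- ncol(els)
  ndof <- 3L * nn
  quad <- tet_quadrature(mesh$order)
  nq <- length(quad$w)
  nodes <- mesh$nodes
  nt <- ne * ndof * ndof
  ti <- integer(nt); tj <- integer(nt); tx <- numeric(nt)
  pos <- 0L
  dof_of <- function(n) rbind(3L * n - 2L, 3L * n - 1L, 3L * n)
  dNdXi_q <- lapply(seq_len(nq), function(q) ref_shape_derivs(quad$bary[q, ], mesh$order))
  for (e in seq_len(ne)) {
    X <- nodes[els[e, ], , drop = FALSE]
    ke <- matrix(0, ndof, ndof)
    for (q in seq_len(nq)) {
      ig <- iso_gradients(X, dNdXi_q[[q]])
      if (ig$detJ <= 0) abort("inverted element detected during assembly")
      B <- strain_displacement_matrix(ig$G)
      ke <- ke + (quad$w[q] * ig$detJ / 6) * crossprod(B, D %*% B)
    }
    dofs <- as.integer(dof_of(els[e, ]))
    idx <- pos + seq_len(ndof * ndof)
    ti[idx] <- rep(dofs, times = ndof)
    tj[idx] <- rep(dofs, each = ndof)
    tx[idx] <- ke
    pos <- pos + ndof * ndof
  }
  Matrix::sparseMatrix(i = ti, j = tj, x = tx,
                       dims = rep(3L * nrow(nodes), 2))
}

resolve_boundary_values <- function(fn, points, what) {
  if (is.null(fn)) return(matrix(0, nrow(points), 3))
  if (identical(fn, "zero")) return(matrix(0, nrow(points), 3))
  if (inherits(fn, "displacement_interpolator")) {
    return(interp_eval(fn, points))
  }
  if (is.function(fn)) {
    u <- fn(points)
    if (is.data.frame(u)) u <- cbind(u$ux, u$uy, u$uz)
    u <- as.matrix(u)
    if (nrow(u) != nrow(points) || ncol(u) != 3L) {
      abort(sprintf("%s function must return an n x 3 displacement matrix", what))
    }
    if (!all(is.finite(u))) abort(sprintf("%s displacements must be finite", what))
    return(u)
  }
  if (is.numeric(fn) && length(fn) == 3L) {
    return(matrix(fn, nrow(points), 3, byrow = TRUE))
  }
  abort(sprintf("cannot interpret %s boundary condition", what))
}

#' Solve the displacement boundary-value problem on a gel mesh
#'
#' Static isotropic linear elasticity (`div T = 0`, `T = 2 mu eps + lambda
#' tr(eps) I`) with Dirichlet data: interpolated (measured) displacements on
#' the tissue-gel interface and, by default, zero displacement on the outer
#' gel boundary. This is the direct forward solve used to reconstruct the
#' stress state of the gel from bead-measured interface motion.
#'
#' @param mesh A [build_gel_mesh()] result.
#' @param material An [elastic_material()].
#' @param interface_displacement Dirichlet data on the interface: a
#'   [displacement_interpolator()], a `function(points) -> n x 3`, a constant
#'   length-3 vector, or `"zero"`.
#' @param outer_condition Same forms, for the outer boundary; default
#'   `"zero"`.
#' @return A `fem_solution`: list with `mesh`, `material`, `U` (N x 3 nodal
#'   displacements, um), `constrained` (dof indices).
#' @export
solve_displacement_bvp <- function(mesh, material, interface_displacement,
                                   outer_condition = "zero") {
  stopifnot(inherits(mesh, "gel_mesh"))
  material <- as_material(material)
  K <- assemble_stiffness(mesh, material)
  N <- nrow(mesh$nodes)
  u <- matrix(0, N, 3)
  u[mesh$interface_nodes, ] <- resolve_boundary_values(
    interface_displacement, mesh$nodes[mesh$interface_nodes, , drop = FALSE],
    "interface")
  u[mesh$outer_nodes, ] <- resolve_boundary_values(
    outer_condition, mesh$nodes[mesh$outer_nodes, , drop = FALSE], "outer")
  fixed_nodes <- union(mesh$interface_nodes, mesh$outer_nodes)
  fixed <- as.integer(t(cbind(3L * fixed_nodes - 2L, 3L * fixed_nodes - 1L,
                              3L * fixed_nodes)))
  free <- setdiff(seq_len(3L * N), fixed)
  if (length(free) == 0L) {
    sol <- u
  } else {
    uc <- as.vector(t(u))[fixed]
    rhs <- -K[free, fixed, drop = FALSE] %*% uc
    Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
    uf <- tryCatch(
      as.vector(Matrix::solve(Matrix::Cholesky(Kff, LDL = FALSE), rhs)),
      error = function(e) abort(paste("linear solve failed:", conditionMessage(e)))
    )
    if (!all(is.finite(uf))) abort("linear solve produced non-finite values")
    full <- numeric(3L * N)
    full[fixed] <- uc
    full[free] <- uf
    sol <- matrix(full, N, 3, byrow = TRUE)
  }
  structure(list(mesh = mesh, material = material, U = sol,
                 constrained = fixed),
            class = "fem_solution")
}

#' @export
print.fem_solution <- function(x, ...) {
  cat(sprintf("<fem_solution> %d nodes, max |u| = %.4g um\n",
              nrow(x$U), max(sqrt(rowSums(x$U^2)))))
  invisible(x)
}

# Strain (engineering, 6-vector) of one element evaluated at barycentric
# coordinates `L`; `ue` is the element displacement vector (3*nn) and `X`
# the element node coordinates.
element_strain <- function(X, order, L, ue) {
  ig <- iso_gradients(X, ref_shape_derivs(L, order))
  as.vector(strain_displacement_matrix(ig$G) %*% ue)
}

#' Cauchy stress field from a solved displacement problem
#'
#' Applies Hooke's law to the element strains and recovers nodal values by
#' volume-weighted averaging over the elements adjacent to each node.
#'
#' @param solution A [solve_displacement_bvp()] result.
#' @return A `stress_field` tibble: `node, x, y, z, Txx, Tyy, Tzz, Txy, Tyz,
#'   Txz` (Pa), with the mesh attached as an attribute.
#' @export
cauchy_stress <- function(solution) {
  stopifnot(inherits(solution, "fem_solution"))
  mesh <- solution$mesh
  D <- stiffness_matrix(solution$material)
  els <- mesh$elements
  ne <- nrow(els)
  nn <- ncol(els)
  # barycentric coordinates of the element nodes
  corn <- diag(4)
  locL <- if (mesh$order == 2L) {
    edges <- rbind(c(1, 2), c(2, 3), c(3, 1), c(1, 4), c(2, 4), c(3, 4))
    rbind(corn, (corn[edges[, 1], ] + corn[edges[, 2], ]) / 2)
  } else corn
  N <- nrow(mesh$nodes)
  acc <- matrix(0, N, 6)
  wacc <- numeric(N)
  Uvec <- t(solution$U)
  dNdXi_loc <- lapply(seq_len(nn), function(a) ref_shape_derivs(locL[a, ], mesh$order))
  for (e in seq_len(ne)) {
    en <- els[e, ]
    X <- mesh$nodes[en, , drop = FALSE]
    ue <- as.vector(Uvec[, en])
    v <- mesh$volumes[e]
    for (a in seq_len(nn)) {
      ig <- iso_gradients(X, dNdXi_loc[[a]])
      sig <- as.vector(D %*% (strain_displacement_matrix(ig$G) %*% ue))
      acc[en[a], ] <- acc[en[a], ] + v * sig
      wacc[en[a]] <- wacc[en[a]] + v
    }
  }
  S <- acc / wacc
  out <- tibble(
    node = seq_len(N),
    x = mesh$nodes[, 1], y = mesh$nodes[, 2], z = mesh$nodes[, 3],
    Txx = S[, 1], Tyy = S[, 2], Tzz = S[, 3],
    Txy = S[, 4], Tyz = S[, 5], Txz = S[, 6]
  )
  attr(out, "mesh") <- mesh
  class(out) <- c("stress_field", class(out))
  out
}

#' Surface tractions on the tissue-gel interface
#'
#' Computes the stress (traction) vector `t = T n` at every interface node,
#' with `n` the outward unit normal of the tissue surface (pointing into the
#' gel), together with its magnitude `|t|` and normal component
#' `t_n = t . n`. Under the package's tensile convention `t_n > 0` means the
#' interface is under tension (the migrating tissue pulls the matrix toward
#' itself).
#'
#' @param stress A [cauchy_stress()] result (or a `fem_solution`, in which
#'   case the stress is computed first).
#' @return A `traction_field` tibble: `node, x, y, z, nx, ny, nz, tx, ty, tz,
#'   t_mag, t_n, area` (Pa; area in um^2), one row per interface node.
#' @export
surface_tractions <- function(stress) {
  if (inherits(stress, "fem_solution")) stress <- cauchy_stress(stress)
  mesh <- attr(stress, "mesh")
  if (is.null(mesh)) abort("stress field lacks its mesh attribute")
  ids <- mesh$interface_nodes
  S <- unname(as.matrix(stress[ids, c("Txx", "Tyy", "Tzz", "Txy", "Tyz", "Txz")]))
  nrm <- unname(mesh$interface_normals)
  tx <- S[, 1] * nrm[, 1] + S[, 4] * nrm[, 2] + S[, 6] * nrm[, 3]
  ty <- S[, 4] * nrm[, 1] + S[, 2] * nrm[, 2] + S[, 5] * nrm[, 3]
  tz <- S[, 6] * nrm[, 1] + S[, 5] * nrm[, 2] + S[, 3] * nrm[, 3]
  t_n <- tx * nrm[, 1] + ty * nrm[, 2] + tz * nrm[, 3]
  out <- tibble(
    node = ids,
    x = mesh$nodes[ids, 1], y = mesh$nodes[ids, 2], z = mesh$nodes[ids, 3],
    nx = nrm[, 1], ny = nrm[, 2], nz = nrm[, 3],
    tx = tx, ty = ty, tz = tz,
    t_mag = sqrt(tx^2 + ty^2 + tz^2), t_n = t_n,
    area = mesh$interface_areas
  )
  attr(out, "mesh") <- mesh
  class(out) <- c("traction_field", class(out))
  out
}

#' Net force transmitted across the interface
#'
#' Area-weighted integral of the traction vector over the tissue surface
#' (Pa um^2). For a loading that transmits no net force to the far field this
#' should vanish up to discretization error.
#'
#' @param tractions A [surface_tractions()] result.
#' @return Length-3 numeric force vector.
#' @export
net_interface_force <- function(tractions) {
  c(sum(tractions$tx * tractions$area),
    sum(tractions$ty * tractions$area),
    sum(tractions$tz * tractions$area))
}

#' Per-region traction localization statistics
#'
#' Summarizes how traction concentrates over labelled regions of the tissue
#' surface. The top decile is defined by area: the minimal set of
#' highest-`|t|` nodes (ties broken by node index) whose lumped areas cover
#' 10% of the surface, so for a uniform field it carries exactly one tenth
#' of the area. Reported per region: mean and max `|t|`, the share of
#' top-decile nodes, the area fraction carrying the top decile, and the
#' tensile fraction (share of nodes with `t_n > 0`).
#'
#' @param tractions A [surface_tractions()] result.
#' @param regions Vector of region labels, one per traction row; must label
#'   every node (a partition of the surface).
#' @return Tibble with one row per region.
#' @export
traction_localization_summary <- function(tractions, regions) {
  if (length(regions) != nrow(tractions)) {
    abort("`regions` must label every interface node (partition of the surface)")
  }
  if (anyNA(regions)) abort("`regions` must not contain NA")
  ord <- order(-tractions$t_mag, tractions$node)
  cum_area <- cumsum(tractions$area[ord])
  n_top <- which(cum_area >= 0.1 * sum(tractions$area))[1]
  top <- logical(nrow(tractions))
  top[ord[seq_len(n_top)]] <- TRUE
  df <- tractions %>%
    mutate(region = regions, top_decile = top) %>%
    group_by(.data$region) %>%
    summarise(
      n_nodes = dplyr::n(),
      mean_t = mean(.data$t_mag),
      max_t = max(.data$t_mag),
      top_decile_share = sum(.data$top_decile) / sum(top),
      top_decile_area_fraction = sum(.data$area[.data$top_decile]) / sum(.data$area),
      tensile_fraction = mean(.data$t_n > 0),
      .groups = "drop"
    )
  df
}
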