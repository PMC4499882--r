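#' Triangulated tissue surfaces
#'
#' A `tissue_surface` is a watertight triangulated surface (vertices in um,
#' faces with consistent outward winding) representing the epithelium-matrix
#' interface. `surface_sphere()` builds an icosphere, the idealized tissue
#' used throughout verification; arbitrary star-shaped surfaces can be
#' constructed with `tissue_surface()`.
#'
#' @param vertices n x 3 matrix, um.
#' @param faces f x 3 integer matrix, outward (counter-clockwise seen from
#'   outside) winding.
#' @param radius Sphere radius, um.
#' @param center Center, um.
#' @param subdivisions Icosphere subdivision level (0 = icosahedron,
#'   each level quadruples the face count).
#' @return A `tissue_surface`: list with `vertices`, `faces`, `normals`
#'   (per-vertex outward unit normals), `center`.
#' @export
tissue_surface <- function(vertices, faces, center = colMeans(vertices)) {
  vertices <- as_point_matrix(vertices, "vertices")
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3L) abort("`faces` must be f x 3")
  if (!surface_is_watertight(faces)) {
    abort("surface is not watertight: every edge must be shared by exactly two faces")
  }
  structure(
    list(vertices = vertices, faces = faces,
         normals = vertex_normals(vertices, faces),
         center = as.numeric(center)),
    class = "tissue_surface"
  )
}

#' @rdname tissue_surface
#' @export
surface_sphere <- function(radius = 50, center = c(0, 0, 0), subdivisions = 1L) {
  ico <- icosphere(subdivisions)
  tissue_surface(sweep(ico$vertices * radius, 2, center, `+`), ico$faces,
                 center = center)
}

#' @export
print.tissue_surface <- function(x, ...) {
  cat(sprintf("<tissue_surface> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

surface_is_watertight <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

vertex_normals <- function(vertices, faces) {
  v1 <- vertices[faces[, 1], , drop = FALSE]
  v2 <- vertices[faces[, 2], , drop = FALSE]
  v3 <- vertices[faces[, 3], , drop = FALSE]
  fn <- cross3(v2 - v1, v3 - v1)  # area-weighted face normals
  nrm <- matrix(0, nrow(vertices), 3)
  for (j in 1:3) {
    for (k in 1:3) {
      acc <- rowsum(fn[, k], faces[, j])
      ii <- as.integer(rownames(acc))
      nrm[ii, k] <- nrm[ii, k] + acc[, 1]
    }
  }
  nrm / sqrt(rowSums(nrm^2))
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

triangle_areas <- function(vertices, faces) {
  v1 <- vertices[faces[, 1], , drop = FALSE]
  v2 <- vertices[faces[, 2], , drop = FALSE]
  v3 <- vertices[faces[, 3], , drop = FALSE]
  0.5 * sqrt(rowSums(cross3(v2 - v1, v3 - v1)^2))
}

# Unit icosphere: icosahedron refined `n` times with midpoint subdivision.
icosphere <- function(n = 1L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (it in seq_len(n)) {
    nv <- nrow(v)
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    key <- pmin(e[, 1], e[, 2]) * (nv + 1) + pmax(e[, 1], e[, 2])
    uk <- unique(key)
    mid_id <- match(key, uk) + nv
    first <- match(uk, key)
    mids <- (v[e[first, 1], , drop = FALSE] + v[e[first, 2], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    nf <- nrow(f)
    m12 <- mid_id[seq_len(nf)]
    m23 <- mid_id[nf + seq_len(nf)]
    m31 <- mid_id[2 * nf + seq_len(nf)]
    f <- rbind(cbind(f[, 1], m12, m31),
               cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23),
               cbind(m12, m23, m31))
  }
  list(vertices = v, faces = f)
}

#' Mesh the gel domain around a tissue surface
#'
#' Builds a conforming tetrahedral mesh of the gel between the tissue surface
#' and the outer gel boundary (default: the 2000 um cylinder representing the
#' collagen gel) by extruding the surface triangulation radially. Shell radii
#' are log-spaced so the element size grows proportionally to the distance
#' from the interface, concentrating refinement where the displacement field
#' varies fastest; each prism between consecutive shells is split into three
#' tetrahedra with globally consistent diagonals, and quadratic (10-node)
#' elements are formed by inserting edge midpoints. The surface must be
#' star-shaped about its center.
#'
#' @param surface A [tissue_surface()], strictly inside `outer`.
#' @param outer Outer gel boundary, a [gel_cylinder()] or [gel_box()].
#' @param n_layers Number of radial element layers.
#' @param order Element order: 2 (quadratic, default) or 1 (linear).
#' @param curved For order 2, project midside nodes onto the curved shells
#'   (isoparametric elements; default). `curved = FALSE` keeps straight
#'   (affine) elements, for which the patch test is exact to solver
#'   tolerance but the faceted interface under-resolves surface stress.
#' @return A `gel_mesh`: list with `nodes` (N x 3, um), `elements`
#'   (E x 4 or E x 10 node indices), `order`, `interface_nodes`,
#'   `outer_nodes`, `interface_facets` (corner ids; plus `interface_facet_mids`
#'   for order 2), `interface_normals` (one row per interface node), and
#'   bookkeeping fields.
#' @export
build_gel_mesh <- function(surface, outer = gel_cylinder(radius = 1000, height = 2000),
                           n_layers = 8L, order = 2L, curved = TRUE) {
  stopifnot(inherits(surface, "tissue_surface"))
  if (!order %in% c(1L, 2L)) abort("`order` must be 1 or 2")
  if (n_layers < 1L) abort("`n_layers` must be >= 1")
  ctr <- surface$center
  V <- surface$vertices
  nv <- nrow(V)
  dirs <- sweep(V, 2, ctr)
  r0 <- sqrt(rowSums(dirs^2))
  if (any(r0 <= 0)) abort("surface center coincides with a vertex")
  dirs <- dirs / r0
  Rout <- ray_exit_distance(outer, ctr, dirs)
  if (any(r0 >= Rout * (1 - 1e-9))) {
    abort("surface must lie strictly inside the outer gel boundary")
  }
  L <- as.integer(n_layers)
  # shell radii, log-spaced per vertex: r_k = r0 (R/r0)^(k/L)
  nodes <- matrix(0, nv * (L + 1L), 3)
  for (k in 0:L) {
    rk <- r0 * (Rout / r0)^(k / L)
    nodes[k * nv + seq_len(nv), ] <- sweep(dirs * rk, 2, ctr, `+`)
  }
  # prisms -> 3 tets with columns ordered by surface vertex index
  f <- t(apply(surface$faces, 1, sort))
  nf <- nrow(f)
  tets <- matrix(0L, 3L * nf * L, 4L)
  row <- 0L
  for (k in seq_len(L)) {
    b <- (k - 1L) * nv
    tp <- k * nv
    b0 <- b + f[, 1]; b1 <- b + f[, 2]; b2 <- b + f[, 3]
    t0 <- tp + f[, 1]; t1 <- tp + f[, 2]; t2 <- tp + f[, 3]
    tets[row + seq_len(nf), ] <- cbind(b0, b1, b2, t0)
    tets[row + nf + seq_len(nf), ] <- cbind(b1, b2, t0, t1)
    tets[row + 2L * nf + seq_len(nf), ] <- cbind(b2, t0, t1, t2)
    row <- row + 3L * nf
  }
  # enforce positive orientation (swap two nodes where the volume is negative)
  vol <- tet_volumes(nodes, tets)
  neg <- vol < 0
  if (any(neg)) tets[neg, c(3, 4)] <- tets[neg, c(4, 3)]
  vol <- abs(vol)
  if (any(vol < 1e-12)) abort("meshing failure: degenerate (zero-volume) element")

  interface_nodes <- seq_len(nv)
  outer_nodes <- L * nv + seq_len(nv)
  mesh <- list(nodes = nodes, tets = tets, order = order,
               interface_nodes = interface_nodes, outer_nodes = outer_nodes,
               interface_facets = surface$faces, surface = surface,
               outer = outer, n_layers = L, volumes = vol)

  if (order == 2L) {
    ne <- nrow(tets)
    locedge <- rbind(c(1, 2), c(2, 3), c(3, 1), c(1, 4), c(2, 4), c(3, 4))
    ei <- matrix(0L, ne * 6L, 2L)
    for (m in 1:6) {
      ei[(m - 1L) * ne + seq_len(ne), ] <- cbind(tets[, locedge[m, 1]],
                                                 tets[, locedge[m, 2]])
    }
    a <- pmin(ei[, 1], ei[, 2]); bb <- pmax(ei[, 1], ei[, 2])
    key <- a * (nrow(nodes) + 1) + bb  # numeric key, exact for our sizes
    uk <- unique(key)
    mid_of_edge <- match(key, uk)
    first <- match(uk, key)
    # Midside nodes. With `curved`, edges joining two nodes of the same
    # radial shell are projected onto that shell's curved geometry (the
    # log-interpolated radius between the surface and the ray exit of the
    # outer domain along the bisector direction), so interface edges follow
    # the tissue surface and outer edges the gel boundary; radial and
    # diagonal edges keep their straight midpoints. Elements are treated
    # isoparametrically downstream.
    ea <- a[first]; eb <- bb[first]
    p1 <- nodes[ea, , drop = FALSE]
    p2 <- nodes[eb, , drop = FALSE]
    midnodes <- (p1 + p2) / 2
    if (curved) {
      # Every edge midpoint moves to the bisector direction at the mean
      # endpoint radius, so the whole mesh curves consistently with its
      # radial shells (purely radial edges are unchanged; interface edges
      # follow the tissue surface, which is what matters for traction
      # recovery). The outer boundary, where the data is a homogeneous
      # Dirichlet condition, stays faceted between its vertex nodes:
      # snapping midnodes onto the cylinder bends elements that straddle
      # the wall/cap edge ring and can invert them under refinement, for a
      # geometric gain of order (a/R)^3 in the solution.
      q1 <- sweep(p1, 2, ctr)
      q2 <- sweep(p2, 2, ctr)
      dmid <- q1 + q2
      dmid <- dmid / sqrt(rowSums(dmid^2))
      rad <- (sqrt(rowSums(q1^2)) + sqrt(rowSums(q2^2))) / 2
      midnodes <- sweep(dmid * rad, 2, ctr, `+`)
    }
    nbase <- nrow(nodes)
    mesh$nodes <- rbind(nodes, midnodes)
    elements <- cbind(tets, matrix(0L, ne, 6L))
    for (m in 1:6) {
      elements[, 4L + m] <- nbase + mid_of_edge[(m - 1L) * ne + seq_len(ne)]
    }
    mesh$elements <- elements
    # midside nodes whose parent vertices are both on a boundary shell lie on
    # that shell (shell vertices are only joined within shell facets)
    on_if <- a <= nv & bb <= nv
    on_out <- a > (L * nv) & a <= (L + 1L) * nv & bb > (L * nv) & bb <= (L + 1L) * nv
    if_mids <- unique(nbase + mid_of_edge[on_if])
    out_mids <- unique(nbase + mid_of_edge[on_out])
    mesh$interface_nodes <- c(interface_nodes, sort(if_mids))
    mesh$outer_nodes <- c(outer_nodes, sort(out_mids))
    # midside ids per interface facet (for facet quadrature)
    fe <- surface$faces
    fk <- function(i, j) pmin(i, j) * (nbase + 1) + pmax(i, j)
    mesh$interface_facet_mids <- cbind(
      nbase + mid_of_edge[match(fk(fe[, 1], fe[, 2]), key)],
      nbase + mid_of_edge[match(fk(fe[, 2], fe[, 3]), key)],
      nbase + mid_of_edge[match(fk(fe[, 3], fe[, 1]), key)]
    )
  } else {
    mesh$elements <- tets
  }
  mesh$interface_normals <- interface_node_normals(mesh)
  mesh$interface_areas <- interface_node_areas(mesh)
  class(mesh) <- "gel_mesh"
  mesh
}

#' @export
print.gel_mesh <- function(x, ...) {
  cat(sprintf(
    "<gel_mesh> %d nodes, %d P%d tetrahedra, %d interface / %d outer boundary nodes\n",
    nrow(x$nodes), nrow(x$elements), x$order,
    length(x$interface_nodes), length(x$outer_nodes)))
  invisible(x)
}

tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 2], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 3], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  cc <- nodes[tets[, 4], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  rowSums(cross3(a, b) * cc) / 6
}

# Outward unit normal per interface node (vertex normals from the surface;
# midside nodes average their edge endpoints' normals).
interface_node_normals <- function(mesh) {
  s <- mesh$surface
  vn <- s$normals
  ids <- mesh$interface_nodes
  nrm <- matrix(NA_real_, length(ids), 3)
  nv <- nrow(s$vertices)
  corner <- ids <= nv
  nrm[corner, ] <- vn[ids[corner], , drop = FALSE]
  if (any(!corner) && !is.null(mesh$interface_facet_mids)) {
    fe <- s$faces
    mids <- mesh$interface_facet_mids
    pairs <- rbind(cbind(mids[, 1], fe[, 1], fe[, 2]),
                   cbind(mids[, 2], fe[, 2], fe[, 3]),
                   cbind(mids[, 3], fe[, 3], fe[, 1]))
    pairs <- pairs[!duplicated(pairs[, 1]), , drop = FALSE]
    mloc <- match(ids[!corner], pairs[, 1])
    mn <- vn[pairs[mloc, 2], , drop = FALSE] + vn[pairs[mloc, 3], , drop = FALSE]
    nrm[!corner, ] <- mn / sqrt(rowSums(mn^2))
  }
  rownames(nrm) <- ids
  nrm
}

# Lumped area per interface node: each facet contributes A/3 to its corners
# (order 1) or A/6 to corners and A/6 to midside nodes (order 2); used for
# area-weighted summaries and net-force integrals.
interface_node_areas <- function(mesh) {
  s <- mesh$surface
  A <- triangle_areas(s$vertices, s$faces)
  ids <- mesh$interface_nodes
  w <- setNames(numeric(length(ids)), ids)
  add <- function(w, node_ids, contrib) {
    acc <- rowsum(contrib, node_ids)
    keys <- rownames(acc)
    w[keys] <- w[keys] + acc[, 1]
    w
  }
  if (mesh$order == 2L) {
    for (j in 1:3) w <- add(w, s$faces[, j], A / 6)
    for (j in 1:3) w <- add(w, mesh$interface_facet_mids[, j], A / 6)
  } else {
    for (j in 1:3) w <- add(w, s$faces[, j], A / 3)
  }
  unname(w)
}
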