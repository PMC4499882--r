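test_that("gel meshes are valid, tagged and conforming", {
  mesh <- sphere_mesh(n_layers = 3, subdiv = 0)
  expect_s3_class(mesh, "gel_mesh")
  expect_true(all(mesh$volumes > 0))
  # interface corner nodes at radius 50 (tolerance: faceting is exact at vertices)
  rint <- sqrt(rowSums(mesh$nodes[mesh$interface_nodes, ]^2))
  expect_equal(max(abs(rint - 50)), 0, tolerance = 1e-9)
  # outer vertex nodes sit exactly on the cylinder boundary; midside nodes
  # follow the faceted outer shell (within the facet sagitta)
  nv <- nrow(mesh$surface$vertices)
  qv <- mesh$nodes[mesh$outer_nodes[seq_len(nv)], ]
  on_wall <- abs(sqrt(qv[, 1]^2 + qv[, 2]^2) - 1000) < 1e-6
  on_cap <- abs(abs(qv[, 3]) - 1000) < 1e-6
  expect_true(all(on_wall | on_cap))
  qm <- mesh$nodes[mesh$outer_nodes, ]
  expect_lt(max(1000 - pmax(sqrt(qm[, 1]^2 + qm[, 2]^2), abs(qm[, 3]))), 300)
  # normals are outward radial for a sphere
  ids <- mesh$interface_nodes
  rhat <- mesh$nodes[ids, ] / sqrt(rowSums(mesh$nodes[ids, ]^2))
  expect_gt(min(rowSums(rhat * mesh$interface_normals)), 0.99)
  # lumped interface areas integrate to the faceted sphere area
  expect_equal(sum(mesh$interface_areas),
               sum(tfm3d:::triangle_areas(mesh$surface$vertices,
                                          mesh$surface$faces)))
  # a surface exceeding the gel domain is rejected
  expect_error(build_gel_mesh(surface_sphere(50, subdivisions = 0),
                              gel_cylinder(radius = 40, height = 2000), 2),
               "strictly inside")
})

test_that("icosphere surfaces are watertight with outward winding", {
  s <- surface_sphere(50, subdivisions = 1)
  expect_true(tfm3d:::surface_is_watertight(s$faces))
  expect_equal(nrow(s$faces), 80)
  # outward winding: vertex normals point away from the center
  expect_gt(min(rowSums(s$normals * s$vertices / 50)), 0.99)
  bad <- s$faces[-1, ]
  expect_error(tissue_surface(s$vertices, bad), "watertight")
})

test_that("patch test: affine Dirichlet data is reproduced exactly", {
  m <- default_material()
  A <- matrix(c(0.01, 0.002, 0, 0.003, -0.005, 0.001, 0, 0.002, 0.004), 3,
              byrow = TRUE)
  aff <- function(p) p %*% t(A)
  # straight (affine) elements: exact to solver tolerance
  for (order in c(1L, 2L)) {
    mesh <- sphere_mesh(n_layers = 2, subdiv = 0, order = order,
                        curved = FALSE)
    sol <- solve_displacement_bvp(mesh, m, aff, outer_condition = aff)
    expect_lt(max(abs(sol$U - mesh$nodes %*% t(A))), 1e-10)
    st <- cauchy_stress(sol)
    eps <- (A + t(A)) / 2
    Tex <- 2 * m$mu * eps + m$lambda * sum(diag(eps)) * diag(3)
    expect_equal(st$Txx, rep(Tex[1, 1], nrow(st)), tolerance = 1e-8)
    expect_equal(st$Txy, rep(Tex[1, 2], nrow(st)), tolerance = 1e-8)
    expect_equal(st$Tyz, rep(Tex[2, 3], nrow(st)), tolerance = 1e-8)
  }
  # curved isoparametric elements pass to quadrature-consistency level even
  # on a deliberately coarse, strongly curved mesh
  meshc <- sphere_mesh(n_layers = 2, subdiv = 0)
  solc <- solve_displacement_bvp(meshc, m, aff, outer_condition = aff)
  expect_lt(max(abs(solc$U - meshc$nodes %*% t(A))) / max(abs(solc$U)), 5e-3)
})

test_that("zero Dirichlet data yields the zero solution and zero tractions", {
  m <- default_material()
  mesh <- sphere_mesh(n_layers = 2, subdiv = 0)
  sol <- solve_displacement_bvp(mesh, m, "zero")
  expect_equal(max(abs(sol$U)), 0)
  tr <- surface_tractions(sol)
  expect_equal(max(tr$t_mag), 0)
})

test_that("hydrostatic stress gives t = -p n at every interface node", {
  m <- default_material()
  mesh <- sphere_mesh(n_layers = 2, subdiv = 0, curved = FALSE)
  # isotropic compression: u = c x => T = (2 mu + 3 lambda) c I
  cmp <- -0.01
  sol <- solve_displacement_bvp(mesh, m, function(p) cmp * p,
                                outer_condition = function(p) cmp * p)
  tr <- surface_tractions(sol)
  p_eff <- -(2 * m$mu + 3 * m$lambda) * cmp
  expect_equal(tr$tx, -p_eff * tr$nx, tolerance = 1e-6)
  expect_equal(tr$t_mag, rep(p_eff, nrow(tr)), tolerance = 1e-6)
  expect_equal(tr$t_n, rep(-p_eff, nrow(tr)), tolerance = 1e-6)
  expect_equal(mean(tr$t_n > 0), 0)  # compression is not tensile
})

test_that("tractions scale linearly with the interface displacement", {
  m <- default_material()
  mesh <- sphere_mesh(n_layers = 3, subdiv = 0)
  bc <- cavity_bc(m, 50, 100)
  t1 <- surface_tractions(solve_displacement_bvp(mesh, m, bc))
  t3 <- surface_tractions(solve_displacement_bvp(
    mesh, m, function(p) 3 * bc(p)))
  expect_equal(t3$tx, 3 * t1$tx, tolerance = 1e-8)
  expect_equal(t3$t_mag, 3 * t1$t_mag, tolerance = 1e-8)
})

test_that("cavity tractions are tensile, balanced, and near the applied load", {
  m <- default_material()
  mesh <- sphere_mesh(n_layers = 6)
  tr <- surface_tractions(solve_displacement_bvp(mesh, m, cavity_bc(m, 50, 100)))
  expect_equal(mean(tr$t_n > 0), 1)      # tensile everywhere
  # net force balance within 5% of mean |t| * area
  expect_lt(sqrt(sum(net_interface_force(tr)^2)),
            0.05 * mean(tr$t_mag) * sum(tr$area))
  expect_lt(abs(median(tr$t_mag) - 100) / 100, 0.15)
})

test_that("localization summary partitions regions and handles uniform fields", {
  m <- default_material()
  mesh <- sphere_mesh(n_layers = 2, subdiv = 0, curved = FALSE)
  cmp <- -0.01
  sol <- solve_displacement_bvp(mesh, m, function(p) cmp * p,
                                outer_condition = function(p) cmp * p)
  tr <- surface_tractions(sol)
  regions <- ifelse(tr$z >= 0, "north", "south")
  smry <- traction_localization_summary(tr, regions)
  # uniform |t|: equal region means; top decile covers ~10% of the area
  expect_equal(smry$mean_t[1], smry$mean_t[2], tolerance = 1e-6)
  total_top_area <- sum(smry$top_decile_area_fraction *
                          vapply(split(tr$area, regions), sum, numeric(1))[smry$region])
  expect_equal(total_top_area / sum(tr$area), 0.1,
               tolerance = max(tr$area) / sum(tr$area) / 0.1)
  expect_error(traction_localization_summary(tr, regions[-1]), "partition")
  expect_error(traction_localization_summary(tr, replace(regions, 1, NA)), "NA")
})
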