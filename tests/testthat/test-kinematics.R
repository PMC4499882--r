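test_that("displacement fields reference the force-free configuration", {
  tr <- tibble::tibble(
    bead_id = rep(c("a", "b"), each = 2),
    t = rep(c(0, 2), 2),
    x = c(1, 2, 5, 5), y = c(1, 1, 5, 6), z = c(0, 0, 0, -1)
  )
  f <- displacements_from_tracks(tr, reference_time = 0)
  expect_equal(f$ux, c(1, 0))
  expect_equal(f$uy, c(0, 1))
  expect_equal(f$uz, c(0, -1))
  expect_equal(f$x, c(1, 5))  # sample points are reference positions

  # at the reference time itself the field is all zero
  f0 <- displacements_from_tracks(dplyr::bind_rows(tr, tr[tr$t == 0, ]) |>
                                    dplyr::distinct(), 2)
  expect_true(all(abs(c(f0$ux, f0$uy, f0$uz)) ==
                    abs(c(f$ux, f$uy, f$uz))))

  # a track missing the reference is excluded with a warning
  tr2 <- dplyr::bind_rows(tr, tibble::tibble(bead_id = "c", t = 2,
                                             x = 0, y = 0, z = 0))
  expect_warning(f2 <- displacements_from_tracks(tr2, 0), "excluded")
  expect_equal(sort(unique(f2$bead_id)), c("a", "b"))
  expect_error(
    suppressWarnings(displacements_from_tracks(tr2[tr2$bead_id == "c", ], 0)),
    "reference")
})

test_that("interpolators reproduce samples, constants and affine fields", {
  withr::with_seed(21, {
    pts <- matrix(runif(120, 0, 100), 40, 3)
  })
  # uniform translation reproduces the constant everywhere
  f <- tibble::tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                      ux = 1.5, uy = -2, uz = 0.5)
  for (method in c("gaussian", "polyharmonic", "wendland")) {
    ip <- displacement_interpolator(f, method = method)
    pr <- predict(ip, pts[1:10, ], warn_extrapolation = FALSE)
    expect_equal(pr$ux, rep(1.5, 10), tolerance = 1e-5)
    expect_equal(pr$uz, rep(0.5, 10), tolerance = 1e-5)
  }
  # exact at sample points
  withr::with_seed(22, U <- matrix(rnorm(120), 40, 3))
  f2 <- tibble::tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                       ux = U[, 1], uy = U[, 2], uz = U[, 3])
  ip2 <- displacement_interpolator(f2, method = "polyharmonic", ridge = 0)
  pr2 <- predict(ip2, pts, warn_extrapolation = FALSE)
  expect_equal(as.matrix(pr2[, c("ux", "uy", "uz")]), U, tolerance = 1e-6,
               ignore_attr = TRUE)
  # affine reproduction (polyharmonic has an exact affine tail)
  A <- matrix(c(0.01, 0.002, 0, 0.003, -0.005, 0.001, 0, 0.002, 0.004), 3,
              byrow = TRUE)
  f3 <- f2
  f3[, c("ux", "uy", "uz")] <- pts %*% t(A)
  ip3 <- displacement_interpolator(f3, method = "polyharmonic")
  q <- matrix(c(50, 50, 50, 20, 80, 40), 2, 3, byrow = TRUE)
  expect_equal(as.matrix(predict(ip3, q)[, c("ux", "uy", "uz")]), q %*% t(A),
               tolerance = 1e-6, ignore_attr = TRUE)

  # far-outside queries are flagged as extrapolation
  expect_warning(predict(ip2, c(500, 500, 500)), "extrapolation")
  expect_error(displacement_interpolator(f2[1:3, ]), "at least 4")
  flat <- f2[1:6, ]; flat$z <- 1
  expect_error(displacement_interpolator(flat), "coplanar")
})

test_that("interpolation of the cavity field is accurate and improves with density", {
  m <- default_material()
  med_err <- vapply(c(1e-4, 2e-4, 4e-4), function(dens) {
    sc <- synthetic_scene(m, cavity_load(50, 100),
                          gel_box(c(-80, -80, -80), c(80, 80, 80)),
                          bead_density = dens, noise_sigma = 0, seed = 31)
    tr <- synthesize_bead_tracks(sc, c(0, 2), c(0, 1))
    f <- displacements_from_tracks(tr, 0, time = 2)
    ip <- displacement_interpolator(f)
    g <- as.matrix(expand.grid(x = seq(-75, 75, 10), y = seq(-75, 75, 10),
                               z = seq(-75, 75, 10)))
    g <- g[sqrt(rowSums(g^2)) >= 55, ]
    pr <- predict(ip, g, warn_extrapolation = FALSE)
    ex <- cavity_displacement_field(g, m, 50, 100)
    median(sqrt(rowSums((pr[, 4:6] - ex[, 4:6])^2)) /
             sqrt(rowSums(ex[, 4:6]^2)))
  }, numeric(1))
  expect_lt(med_err[3], 0.10)       # within 10% at the study bead density
  expect_true(all(diff(med_err) < 0))  # error decreases with density
})

test_that("displacement gradients and strain tensors follow the closed forms", {
  # affine field: central differences exact regardless of h
  A <- matrix(c(0.02, 0.01, 0, -0.005, 0.03, 0.002, 0.001, 0, 0.015), 3,
              byrow = TRUE)
  aff <- function(p) p %*% t(A)
  for (h in c(0.1, 1, 5)) {
    dg <- displacement_gradient(aff, c(10, 20, 30), h = h)
    expect_equal(dg$grad_u, A, tolerance = 1e-9)
  }
  expect_error(displacement_gradient(aff, c(0, 0, 0), h = 0), "positive")

  # zero field
  dg0 <- displacement_gradient(function(p) 0 * p, c(1, 1, 1))
  expect_equal(dg0$F, diag(3))
  expect_equal(green_lagrange(dg0), matrix(0, 3, 3))

  # Green-Lagrange of rigid motions vanishes; small strain does not
  withr::with_seed(41, {
    for (i in 1:5) {
      ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
      th <- runif(1, 0.1, 1)
      K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3,
                  byrow = TRUE)
      R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
      tr <- rnorm(3, sd = 5)
      rig <- function(p) p %*% t(R) - p + matrix(tr, nrow(p), 3, byrow = TRUE)
      dg <- displacement_gradient(rig, rnorm(3), h = 0.5)
      expect_lt(max(abs(green_lagrange(dg))), 1e-12)
    }
  })

  # uniaxial stretch lambda = 1.1
  gu <- diag(c(0.1, 0, 0))
  expect_equal(green_lagrange(gu)[1, 1], 0.105)
  expect_equal(small_strain(gu)[1, 1], 0.1)

  # small-gradient agreement of the two measures
  withr::with_seed(42, g <- matrix(rnorm(9, sd = 0.003), 3))
  E <- green_lagrange(g); e <- small_strain(g)
  expect_lt(norm(E - e, "F"), 1e-4 * norm(e, "F") + 1e-4)

  # symmetry invariants
  expect_equal(E, t(E), tolerance = 1e-15)
  expect_equal(e, t(e), tolerance = 1e-15)
})

test_that("cavity strain has the -2 radial-to-hoop signature on the x axis", {
  m <- default_material()
  cavf <- function(p) as.matrix(cavity_displacement_field(p, m, 50, 100)[, 4:6])
  dg <- displacement_gradient(cavf, c(100, 0, 0), h = 0.5)
  expect_lt(max(abs(dg$grad_u - diag(diag(dg$grad_u)))), 1e-8)  # diagonal
  expect_equal(dg$grad_u[1, 1] / dg$grad_u[2, 2], -2, tolerance = 1e-3)
  st <- strain_table(cavf, rbind(c(100, 0, 0)), h = 0.5)
  expect_equal(st$eps_xx, dg$grad_u[1, 1], tolerance = 1e-10)
})
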