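test_that("bead seeding is a reproducible Poisson process", {
  dom <- gel_box(c(0, 0, 0), c(100, 100, 100))
  b1 <- sample_bead_positions(dom, 4e-4, seed = 3)
  b2 <- sample_bead_positions(dom, 4e-4, seed = 3)
  expect_identical(b1, b2)

  # expected count 400 in a 100^3 box at 4e-4/um^3; check within 3 sigma
  counts <- vapply(1:30, function(s) {
    nrow(sample_bead_positions(dom, 4e-4, seed = s))
  }, numeric(1))
  expect_lt(abs(mean(counts) - 400), 3 * sqrt(400 / 30))

  # Poisson dispersion: variance/mean of counts over 100 seeds in [0.8, 1.2]
  small <- gel_box(c(0, 0, 0), c(50, 50, 50))
  cs <- vapply(1:100, function(s) {
    nrow(sample_bead_positions(small, 4e-4, seed = 1000 + s))
  }, numeric(1))
  expect_gt(var(cs) / mean(cs), 0.8)
  expect_lt(var(cs) / mean(cs), 1.2)

  # disjoint equal-volume boxes get statistically equal counts
  cA <- nrow(sample_bead_positions(gel_box(c(0, 0, 0), c(100, 100, 100)), 4e-4, 5))
  cB <- nrow(sample_bead_positions(gel_box(c(200, 0, 0), c(300, 100, 100)), 4e-4, 6))
  expect_lt(abs(cA - cB), 4 * sqrt(400 + 400))

  expect_error(sample_bead_positions(dom, 0), "positive")
})

test_that("cylinder domains sample inside and report exact volume", {
  cyl <- gel_cylinder(radius = 100, height = 50)
  expect_equal(domain_volume(cyl), pi * 100^2 * 50)
  b <- sample_bead_positions(cyl, 1e-4, seed = 2)
  expect_true(all(domain_contains(cyl, b)))
})

test_that("synthetic bead tracks realize schedule * field + noise", {
  m <- default_material()
  sc <- synthetic_scene(m, cavity_load(50, 100),
                        gel_box(c(-80, -80, -80), c(80, 80, 80)),
                        noise_sigma = 0, seed = 4)
  tr <- synthesize_bead_tracks(sc, c(0, 2, 4), c(0, 0.5, 1))
  f4 <- displacements_from_tracks(tr, 0, time = 4)
  truth <- cavity_displacement_field(f4, m, 50, 100)
  expect_equal(as.matrix(f4[, c("ux", "uy", "uz")]),
               as.matrix(truth[, c("ux", "uy", "uz")]), tolerance = 1e-12,
               ignore_attr = TRUE)
  # half amplitude at t = 2
  f2 <- displacements_from_tracks(tr, 0, time = 2)
  expect_equal(f2$ux, truth$ux / 2, tolerance = 1e-12)
  # no bead inside the tissue
  expect_true(all(sqrt(f4$x^2 + f4$y^2 + f4$z^2) > 50))

  # all-zero schedule: displacements are pure noise with RMS ~ sigma * sqrt(3)
  scn <- synthetic_scene(m, cavity_load(50, 100),
                         gel_box(c(-80, -80, -80), c(80, 80, 80)),
                         noise_sigma = 0.1, seed = 5)
  trn <- synthesize_bead_tracks(scn, c(0, 2), c(0, 0))
  fn <- displacements_from_tracks(trn, 0, time = 2)
  rms <- sqrt(mean(fn$ux^2 + fn$uy^2 + fn$uz^2))
  expect_equal(rms, 0.1 * sqrt(3), tolerance = 0.1)

  expect_error(synthesize_bead_tracks(sc, c(0, 2), c(0.5, 1)), "force-free")
  expect_error(synthesize_bead_tracks(sc, c(2, 0), c(0, 1)), "increasing")
})

test_that("fiber images carry ground-truth angles with the requested stats", {
  # concentrated: >= 95% of true angles within +-10 deg of the mean
  fi <- render_fiber_image(fiber_field_spec(kappa = 100, mean_angle = 30,
                                            n_fibers = 800, seed = 6))
  expect_gte(mean(axial_difference(fi$angles, 30) <= 10), 0.95)
  # isotropic: alignment index of true angles near 0
  f0 <- render_fiber_image(fiber_field_spec(kappa = 0, n_fibers = 800, seed = 7))
  expect_lt(circular_mean(f0$angles, axial = TRUE)$R, 0.1)
  # empty image
  fe <- render_fiber_image(fiber_field_spec(n_fibers = 0, seed = 1))
  expect_identical(fe$angles, numeric(0))
  expect_true(all(fe$image >= 0))
  # reproducibility
  fa <- render_fiber_image(fiber_field_spec(seed = 9))
  fb <- render_fiber_image(fiber_field_spec(seed = 9))
  expect_identical(fa$image, fb$image)
})

test_that("coupled series obey gain, lag and independence by construction", {
  # gain 1, lag 0, no noise: near bead is an affine copy of the length series
  cs <- synthesize_coupled_series(coupled_series_spec(coupling_gain = 1,
                                                      lag = 0, noise_sigma = 0,
                                                      seed = 2))
  y <- cs$beads$displacement[cs$beads$bead_id == "near01"]
  expect_equal(y, cs$cohort$length, tolerance = 1e-12)
  expect_identical(nrow(cs$cohort), length(unique(cs$beads$t)))

  # far beads decorrelated from the cohort: |r| < 0.4 in >= 90% of seeds
  ok <- vapply(1:40, function(s) {
    cs <- synthesize_coupled_series(coupled_series_spec(seed = 400 + s))
    far1 <- cs$beads$displacement[cs$beads$bead_id == "far01"]
    abs(cor(cs$cohort$length, far1)) < 0.4
  }, logical(1))
  expect_gte(mean(ok), 0.9)

  # determinism
  a <- synthesize_coupled_series(coupled_series_spec(seed = 3))
  b <- synthesize_coupled_series(coupled_series_spec(seed = 3))
  expect_identical(a$beads, b$beads)
})

test_that("mask stacks place cohorts at the stated angles", {
  # all cohorts at 0 degrees: support extends east only
  st <- synthesize_mask_stack(n_tissues = 5,
                              angle_dist = list(type = "vonmises", mean = 0,
                                                kappa = 1e6), seed = 1)
  fm <- frequency_map(st)
  outside <- unclass(fm) > 0 & !st$base_shape
  idx <- which(outside, arr.ind = TRUE)
  ctr <- tfm3d:::mask_centroid(st$base_shape)
  expect_true(all(idx[, 2] > ctr["x"]))  # all invasion pixels east of center
  ys <- nrow(st$base_shape) - idx[, 1]
  expect_lt(max(abs(ys - (nrow(st$base_shape) - ctr["y_row"]))), 8)

  # zero cohorts: masks identical to base shape
  st0 <- synthesize_mask_stack(n_tissues = 4, n_cohorts = 0L, seed = 2)
  expect_true(all(vapply(st0$masks, identical, logical(1), st0$base_shape)))
  fm0 <- frequency_map(st0)
  expect_identical(unclass(fm0)[, ], st0$base_shape * 1)
})
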