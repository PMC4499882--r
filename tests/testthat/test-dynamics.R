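test_that("cross-covariance follows the stated estimator conventions", {
  x <- 1:5
  cc <- cross_covariance(x, x, max_lag = 1)
  # biased 1/n covariance with 1/(n-1) sds gives r(0) = (n-1)/n
  expect_equal(cc$ccor[cc$lag == 0], 4 / 5, tolerance = 1e-12)
  cc_m <- cross_covariance(x, x, max_lag = 1, sd_denom = "n")
  expect_equal(cc_m$ccor[cc_m$lag == 0], 1, tolerance = 1e-12)
  cc_u <- cross_covariance(x, x, max_lag = 1, estimator = "unbiased",
                           sd_denom = "n")
  expect_equal(cc_u$ccov[cc_u$lag == 0], mean((x - 3)^2), tolerance = 1e-12)

  # constructed shift: peak at the known lag
  withr::with_seed(61, xx <- cumsum(rnorm(40)))
  yy <- dplyr::lag(xx, 2, default = 0)
  expect_equal(peak_correlation(cross_covariance(xx, yy, max_lag = 5))$peak_lag, 2)

  expect_error(cross_covariance(x, rep(1, 5), max_lag = 1), "zero-variance")
  expect_error(cross_covariance(1:6, 1:6, max_lag = 3), "too short")
})

test_that("cross-covariance equals a brute-force double loop", {
  withr::with_seed(62, {
    for (i in 1:25) {
      n <- sample(12:40, 1)
      x <- rnorm(n); y <- rnorm(n)
      ml <- sample(2:(n %/% 2 - 1), 1)
      got <- cross_covariance(x, y, max_lag = ml)
      want <- ccf_bruteforce(x, y, ml)
      expect_equal(got$ccov, want$ccov, tolerance = 1e-12)
      expect_equal(got$ccor, want$ccor, tolerance = 1e-12)
    }
  })
})

test_that("cross-covariance has the expected symmetries and bounds", {
  withr::with_seed(63, { x <- rnorm(30); y <- rnorm(30) })
  cc <- cross_covariance(x, y, max_lag = 6)
  expect_true(all(abs(cc$ccor) <= 1 + 1e-9))
  # autocorrelation peaks at lag 0
  ac <- cross_covariance(x, x, max_lag = 6)
  expect_equal(ac$lag[which.max(ac$ccor)], 0)
  # c_xy(k) = c_yx(-k)
  cc_rev <- cross_covariance(y, x, max_lag = 6)
  expect_equal(cc$ccov, rev(cc_rev$ccov), tolerance = 1e-12)
  # white-noise null: mean r(0) ~ 0 with SD ~ 1/sqrt(n)
  withr::with_seed(64, {
    r0 <- vapply(1:400, function(i) {
      cross_covariance(rnorm(20), rnorm(20), max_lag = 0)$ccor
    }, numeric(1))
  })
  expect_lt(abs(mean(r0)), 0.02)
  expect_equal(sd(r0), 1 / sqrt(20), tolerance = 0.15)
})

test_that("beads classify as near/far with ties going far", {
  beads <- tibble::tibble(bead_id = c("a", "b", "c"),
                          x = c(10, 200, 50), y = 0, z = 0)
  cls <- classify_beads(beads, rbind(c(0, 0, 0)), threshold = 50)
  expect_equal(cls$class[cls$bead_id == "a"], "near")
  expect_equal(cls$class[cls$bead_id == "b"], "far")
  expect_equal(cls$class[cls$bead_id == "c"], "far")  # exactly 50 -> far
  # minimum over a trajectory: a bead that ever comes near is near
  traj <- tibble::tibble(bead_id = "d", x = c(200, 30), y = 0, z = 0)
  expect_equal(classify_beads(traj, rbind(c(0, 0, 0)))$class, "near")
})

test_that("near/far correlation report recovers coupling and lag", {
  cs <- synthesize_coupled_series(coupled_series_spec(lag = 2, noise_sigma = 0,
                                                      seed = 2))
  rep0 <- suppressWarnings(near_far_correlation_report(cs$cohort, cs$beads))
  near_lag <- rep0$class_summary$modal_lag[rep0$class_summary$class == "near"]
  expect_identical(near_lag, 2L)
  near_r <- rep0$class_summary$mean_peak_r[rep0$class_summary$class == "near"]
  # biased 1/n estimator truncates |k| terms at the edges: peak r ~ (n-k)/n
  n_s <- nrow(cs$cohort) - 1L
  expect_gt(near_r, (n_s - 3) / n_s)
  expect_lt(rep0$p_value, 0.01)
  g <- glance(rep0)
  expect_gt(g$mean_peak_r_near, g$mean_peak_r_far)
  expect_error(near_far_correlation_report(
    cs$cohort, cs$beads[cs$beads$class == "near", ]), "near and far")
})

test_that("cohort length and projected area match constructed masks", {
  mask <- matrix(FALSE, 64, 128)
  mask[30:34, 11:50] <- TRUE  # 40 px long, 5 px wide protrusion
  edge <- list(point = c(10.5, 0), normal = c(1, 0))
  expect_equal(cohort_length(mask, edge, pixel_size = 0.5), 19.75,
               tolerance = 0.3)  # 40 px at 0.5 um/px, pixel-center convention
  expect_equal(cohort_length(mask, edge, pixel_size = 0.5, method = "geodesic"),
               20, tolerance = 1)
  expect_equal(projected_area(mask, 0.5), 200 * 0.25)
  expect_equal(projected_area(matrix(FALSE, 4, 4)), 0)
  expect_warning(L0 <- cohort_length(matrix(FALSE, 64, 64), edge), "empty")
  expect_equal(L0, 0)

  # a growing synthetic cohort: measured lengths track the schedule
  lens <- seq(10, 34, by = 6)
  meas <- vapply(lens, function(L) {
    m <- matrix(FALSE, 64, 64)
    m[30:33, 11:(10 + L)] <- TRUE
    cohort_length(m, list(point = c(10.5, 0), normal = c(1, 0)))
  }, numeric(1))
  expect_true(all(abs(meas - lens) <= 1))
})

test_that("frequency maps are exact rational occupancy fractions", {
  base <- disk_mask(64, 10)
  st <- synthesize_mask_stack(n_tissues = 50, base_shape = base, seed = 8)
  fm <- frequency_map(st)
  expect_true(all(unclass(fm) >= 0 & unclass(fm) <= 1))
  # values are exactly k/50
  ks <- unique(round(unclass(fm) * 50, 10))
  expect_true(all(abs(ks - round(ks)) < 1e-12))
  expect_true(all(unclass(fm)[base] == 1))
  # union dominance: map of all masks >= map of any single mask scaled
  one <- frequency_map(st$masks[1])
  expect_true(all(unclass(fm) >= unclass(one) / 50 - 1e-12))
  # a cohort present in 1 of 50 masks scores exactly 0.02
  masks <- c(list(st$masks[[1]]), rep(list(base), 49))
  fm1 <- frequency_map(masks)
  solo <- st$masks[[1]] & !base
  expect_true(all(unclass(fm1)[solo] == 0.02))
  expect_error(frequency_map(list(base, disk_mask(32, 5))), "identical")
})

test_that("invasion angles anchor to the east convention and recover truth", {
  st0 <- synthesize_mask_stack(n_tissues = 1,
                               angle_dist = list(type = "vonmises", mean = 0,
                                                 kappa = 1e8), seed = 1)
  ia0 <- invasion_angles(st0)
  expect_equal(ia0$n, 1L)
  expect_lt(directional_difference(ia0$angles$angle, 0), 4)

  st <- synthesize_mask_stack(n_tissues = 83,
                              angle_dist = list(type = "vonmises", mean = 90,
                                                kappa = 4), seed = 5)
  ia <- invasion_angles(st)
  expect_lt(directional_difference(ia$circular_mean, 90), 10)
  expect_lt(ia$rayleigh$p.value, 0.01)

  expect_warning(ie <- invasion_angles(synthesize_mask_stack(
    n_tissues = 3, n_cohorts = 0L, seed = 2)), "no cohorts")
  expect_equal(ie$n, 0L)
})

test_that("nuclear/cytoplasmic ratio matches constructed intensities", {
  img <- matrix(100, 32, 32)
  nuc <- matrix(FALSE, 32, 32); nuc[14:18, 14:18] <- TRUE
  cell <- matrix(FALSE, 32, 32); cell[10:22, 10:22] <- TRUE
  expect_equal(nuclear_cytoplasmic_ratio(img, nuc, cell), 1)
  img[nuc] <- 200
  expect_equal(nuclear_cytoplasmic_ratio(img, nuc, cell), 2)
  expect_equal(nuclear_cytoplasmic_ratio(img + 50, nuc, cell, background = 50), 2)
  # noisy synthetic cells recover the true ratio on average
  withr::with_seed(71, {
    ratios <- vapply(1:50, function(i) {
      im <- matrix(rpois(32 * 32, 100), 32, 32)
      im[nuc] <- rpois(sum(nuc), 180)
      nuclear_cytoplasmic_ratio(im, nuc, cell)
    }, numeric(1))
  })
  expect_lt(abs(mean(ratios) - 1.8), 0.1)
  expect_error(nuclear_cytoplasmic_ratio(img, cell, nuc), "inside")
  expect_error(nuclear_cytoplasmic_ratio(img, nuc, nuc), "remainder")
})
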