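test_that("the leave-one-out likelihood is exact at zero deviation", {
  # equally spaced collinear triplet, middle fix on the interpolation line
  tr <- make_track(c(0, 50, 100), c(0, 0, 0), dt_h = 1, error_sd = 0)
  s <- 40
  v <- 2 * 0.25 * s                   # T * alpha * (1 - alpha) * s
  expect_equal(loo_neg_log_likelihood(tr, s), log(2 * pi * v))

  # displaced middle fix: unique interior minimum along a sigma2m sweep
  tr2 <- make_track(c(0, 50, 100), c(0, 30, 0), dt_h = 1, error_sd = 0)
  ss <- exp(seq(log(1), log(1e5), length.out = 200))
  nll <- vapply(ss, function(s) loo_neg_log_likelihood(tr2, s), numeric(1))
  k <- which.min(nll)
  expect_gt(k, 1)
  expect_lt(k, length(ss))
  expect_true(all(diff(nll[1:k]) < 0))
  expect_true(all(diff(nll[k:length(ss)]) > 0))

  expect_error(loo_neg_log_likelihood(make_track(c(0, 1), c(0, 0)), 1),
               "at least 3")
})

test_that("sigma2m estimation recovers the generating variance", {
  sim <- bm_track(sigma2m = 50, n_fixes = 1001, seed = 21)
  est <- estimate_sigma2m(sim$track)
  expect_lt(abs(as.numeric(est) - 50) / 50, 0.15)
  expect_false(attr(est, "boundary"))

  # translation invariance
  tr2 <- sim$track
  tr2$x <- tr2$x + 1000
  tr2$y <- tr2$y - 500
  expect_equal(as.numeric(estimate_sigma2m(tr2)), as.numeric(est))
})

test_that("perfectly interpolated fixes drive sigma2m to the lower bound", {
  # interior fixes sit exactly on the interpolation lines; with delta > 0
  # the likelihood is maximized by motion variance -> 0
  tr <- make_track(seq(0, 1000, by = 50), rep(0, 21), dt_h = 1,
                   error_sd = 5.5)
  est <- estimate_sigma2m(tr)
  expect_true(attr(est, "boundary"))
  expect_lt(as.numeric(est), 1e-6)
})

test_that("inflating the location error never raises the estimate", {
  sim <- bm_track(sigma2m = 50, n_fixes = 301, seed = 22)
  tr_lo <- sim$track
  tr_lo$error_sd <- 2
  tr_hi <- sim$track
  tr_hi$error_sd <- 4
  expect_lte(as.numeric(estimate_sigma2m(tr_hi)),
             as.numeric(estimate_sigma2m(tr_lo)))
})

test_that("window and margin validity rules match the convention", {
  expect_s3_class(dbbmm_config(11, 3), "dbbmm_config")
  expect_error(dbbmm_config(6, 3), "window")
  expect_error(dbbmm_config(11, 0), "margin")
  sim <- bm_track(50, 10, seed = 1)
  expect_error(dbbmm_variance_profile(sim$track, dbbmm_config(11, 3)),
               "shorter")
})

test_that("a constant-variance track yields a flat, consistent profile", {
  ratios <- cvs <- numeric(10)
  for (seed in 1:10) {
    sim <- bm_track(sigma2m = 50, n_fixes = 300, seed = 100 + seed)
    prof <- dbbmm_variance_profile(sim$track)
    full <- as.numeric(estimate_sigma2m(sim$track))
    cvs[seed] <- sd(prof$sigma2m) / mean(prof$sigma2m)
    ratios[seed] <- mean(prof$sigma2m) / full
  }
  expect_lt(median(cvs), 0.5)
  expect_lt(abs(median(ratios) - 1), 0.15)
})

test_that("the profile separates a 10:1 two-state track", {
  sim <- two_state_track(seed = 31, s2 = c(5, 50))
  st <- sim$truth$state
  expect_gt(min(table(st)), 200)
  prof <- dbbmm_variance_profile(sim$track, dbbmm_config(11, 3))
  ratio <- mean(prof$sigma2m[st == "hi"]) / mean(prof$sigma2m[st == "lo"])
  expect_gt(ratio, 3)
})

test_that("margin-blocked breakpoints collapse the profile to the global fit", {
  # window = whole 5-fix track, margin 2: every candidate split leaves a
  # part of fewer than 3 fixes, so no breakpoint is estimable
  tr <- make_track(c(0, 40, 10, 60, 30), c(0, 20, 50, 10, 40), dt_h = 1,
                   error_sd = 0)
  prof <- dbbmm_variance_profile(tr, dbbmm_config(window = 5, margin = 2))
  global <- as.numeric(estimate_sigma2m(tr))
  expect_true(all(abs(prof$sigma2m - global) < 1e-6))
})

test_that("bridge density matches the closed form and integrates to one", {
  d <- bridge_density(T = 1, alpha = 0.5, sigma2m = 100,
                      delta_start = 0, delta_end = 0,
                      start = c(0, 0), end = c(0, 0), at = c(0, 0))
  expect_equal(d, 1 / (2 * pi * 25))   # variance 25 m^2 per axis

  # alpha = 0 with no start error: point mass at the start
  expect_equal(bridge_density(1, 0, 100, 0, 5, c(3, 4), c(50, 60),
                              at = c(3, 4)), Inf)
  expect_equal(bridge_density(1, 0, 100, 0, 5, c(3, 4), c(50, 60),
                              at = c(3.1, 4)), 0)

  # quadrature: density integrates to 1 over a wide grid
  step <- 1
  g <- seq(-80, 120, by = step)
  dens <- outer(g, g, function(x, y) {
    vapply(seq_along(x), function(i) {
      bridge_density(4, 0.3, 100, 5.5, 5.5, c(0, 0), c(40, 20),
                     at = c(x[i], y[i]))
    }, numeric(1))
  })
  expect_equal(sum(dens) * step^2, 1, tolerance = 1e-3)
})

test_that("bridge UDs conserve mass and reduce to the BBMM when constant", {
  sim <- bm_track(sigma2m = 50, n_fixes = 120, seed = 41)
  tr <- sim$track
  grid <- make_reference_grid(tr, 10, 150)
  s2 <- as.numeric(estimate_sigma2m(tr))
  ud_b <- compute_bb_ud(tr, s2, grid)
  expect_equal(sum(ud_b$mass), 1, tolerance = 1e-3)

  const_prof <- tibble::tibble(
    animal_id = tr$animal_id, timestamp = tr$timestamp,
    sigma2m = s2, sigma2m_interval = c(rep(s2, nrow(tr) - 1), NA)
  )
  ud_d <- compute_bb_ud(tr, const_prof, grid)
  expect_lt(max(abs(ud_d$mass - ud_b$mass)), 1e-12)

  expect_error(compute_bb_ud(tr, s2, grid_spec(0, 0, 10, 3, 3)), "cover")
  expect_error(compute_bb_ud(tr, const_prof[1:10, ], grid), "aligned")
})

test_that("a two-fix bridge keeps its mass inside the 4-SD corridor", {
  tr <- make_track(c(0, 200), c(0, 0), dt_h = 1, error_sd = 1)
  grid <- grid_spec(-100, -100, 2, 200, 100)
  ud <- compute_bb_ud(tr, 4, grid, n_alpha = 41)   # tiny sigma2m
  d <- tidy(ud)
  sd_max <- sqrt(1 * 0.25 * 4 + 1)                 # widest node
  corridor <- d$x >= -4 * sd_max & d$x <= 200 + 4 * sd_max &
    abs(d$y) <= 4 * sd_max
  expect_gte(sum(d$mass[corridor]), 0.99)
})

test_that("isopleth areas are stable under grid refinement", {
  sim <- bm_track(sigma2m = 80, n_fixes = 150, seed = 51)
  tr <- sim$track
  coarse <- make_reference_grid(tr, 10, 120)
  fine <- make_reference_grid(tr, 5, 120)
  s2 <- as.numeric(estimate_sigma2m(tr))
  a_coarse <- isopleth_region(compute_bb_ud(tr, s2, coarse), 0.95)$area_ha
  a_fine <- isopleth_region(compute_bb_ud(tr, s2, fine), 0.95)$area_ha
  expect_lt(abs(a_fine - a_coarse) / a_coarse, 0.05)
})

test_that("long gaps can be excluded from bridging", {
  tr <- make_track(c(0, 50, 2000, 2050), c(0, 0, 0, 0),
                   dt_h = c(1, 100, 1), error_sd = 1)
  grid <- make_reference_grid(tr, 10, 100)
  ud_all <- compute_bb_ud(tr, 20, grid)
  ud_cut <- compute_bb_ud(tr, 20, grid, max_lag_h = 10)
  # without the 100 h interval, no mass remains between the two bursts
  mid <- tidy(ud_cut, drop_zero = FALSE)
  between <- mid$x > 300 & mid$x < 1700
  expect_equal(sum(mid$mass[between]), 0)
  expect_gt(sum(tidy(ud_all, drop_zero = FALSE)$mass[between]), 0)
})
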