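test_that("href follows the bivariate normal-reference rule", {
  set.seed(1)
  x <- as.numeric(scale(rnorm(64)))   # exactly unit variance
  y <- as.numeric(scale(rnorm(64)))
  bw <- href_bandwidth(make_track(x, y))
  expect_equal(bw$h_x, 64^(-1 / 6))
  expect_equal(bw$h_y, bw$h_x)

  bw2 <- href_bandwidth(make_track(2 * x, 2 * y))
  expect_equal(bw2$h_x, 2 * bw$h_x)

  expect_error(href_bandwidth(make_track(rep(1, 10), rep(2, 10))),
               "variance")
})

test_that("LSCV converges on smooth data and hits the boundary with duplicates", {
  set.seed(2)
  tr <- make_track(rnorm(80, sd = 100), rnorm(80, sd = 100))
  bw <- lscv_bandwidth(tr)
  expect_true(bw$converged)
  expect_equal(nrow(bw$search_trace), 100)
  expect_equal(bw$search_trace$h[which.min(bw$search_trace$score)], bw$h_x)

  # two tight clusters of exactly coincident fixes: CV decreases as h -> 0
  dup <- make_track(c(rep(0, 20), rep(500, 20)), c(rep(0, 20), rep(0, 20)))
  bw_dup <- lscv_bandwidth(dup)
  expect_false(bw_dup$converged)
  expect_equal(which.min(bw_dup$search_trace$score), 1L)

  expect_error(lscv_bandwidth(make_track(1:4, 1:4)), "at least 5")
})

test_that("the closed-form LSCV criterion matches numerical integration", {
  set.seed(3)
  n <- 10
  tr <- make_track(runif(n, 0, 10), runif(n, 0, 10))
  href <- href_bandwidth(tr)$h_x
  d2 <- rangebridge:::pairwise_sq_dists(tr$x, tr$y)
  for (h in href * c(0.5, 1, 1.5)) {
    # integral of fhat^2 by midpoint quadrature on a wide fine grid
    step <- h / 8
    gx <- seq(min(tr$x) - 8 * h, max(tr$x) + 8 * h, by = step)
    gy <- seq(min(tr$y) - 8 * h, max(tr$y) + 8 * h, by = step)
    Kx <- outer(gx, tr$x, function(c, x) dnorm(c, x, h))
    Ky <- outer(gy, tr$y, function(c, y) dnorm(c, y, h))
    fhat <- (Ky %*% t(Kx)) / n
    int_f2 <- sum(fhat^2) * step^2
    # leave-one-out density at the data points, directly
    loo <- vapply(seq_len(n), function(i) {
      mean(dnorm(tr$x[i], tr$x[-i], h) * dnorm(tr$y[i], tr$y[-i], h))
    }, numeric(1))
    cv_oracle <- int_f2 - 2 * mean(loo)
    cv_closed <- rangebridge:::lscv_score_d2(d2, n, h)
    expect_lt(abs(cv_closed - cv_oracle) / abs(cv_oracle), 1e-6)
  }
})

test_that("plug-in bandwidth approaches the normal-reference rate on Gaussian data", {
  set.seed(4)
  tr <- make_track(rnorm(10000), rnorm(10000))
  bw <- plugin_bandwidth(tr)
  ref <- 1.06 * 10000^(-1 / 5)
  expect_lt(abs(bw$h_x - ref) / ref, 0.15)
  expect_lt(abs(bw$h_y - ref) / ref, 0.15)

  # per-axis equivariance
  tr2 <- tr
  tr2$x <- tr2$x * 3
  bw2 <- plugin_bandwidth(tr2)
  expect_equal(bw2$h_x / bw$h_x, 3, tolerance = 1e-6)
  expect_equal(bw2$h_y, bw$h_y)

  expect_error(plugin_bandwidth(make_track(rnorm(5), rnorm(5))),
               "at least 10")
})

test_that("KDE UD equals the direct kernel mixture and normalizes", {
  grid <- grid_spec(-200, -200, 10, 40, 40)
  one <- make_track(0, 0)
  ud1 <- kde_ud(one, manual_bandwidth(30), grid)
  expect_equal(sum(ud1$mass), 1, tolerance = 1e-6)
  # circular Gaussian: 4-fold symmetric around the origin cell
  expect_equal(ud1$mass[1, 1], ud1$mass[40, 40], tolerance = 1e-12)

  set.seed(5)
  tr <- make_track(rnorm(40, sd = 60), rnorm(40, sd = 60))
  bw <- manual_bandwidth(25)
  ud <- kde_ud(tr, bw, grid)
  xs <- rangebridge:::grid_centers_x(grid)
  ys <- rangebridge:::grid_centers_y(grid)
  cells <- cbind(sample(1:40, 20, replace = TRUE),
                 sample(1:40, 20, replace = TRUE))
  # independent oracle: direct sum-over-points mixture at each cell centre
  dens_total <- sum(
    (outer(ys, tr$y, function(c, y) dnorm(c, y, 25)) %*%
       t(outer(xs, tr$x, function(c, x) dnorm(c, x, 25)))) / nrow(tr)
  )
  for (k in seq_len(nrow(cells))) {
    r <- cells[k, 1]; cc <- cells[k, 2]
    direct <- mean(dnorm(xs[cc], tr$x, 25) * dnorm(ys[r], tr$y, 25))
    oracle_mass <- direct / dens_total
    expect_lt(abs(ud$mass[r, cc] - oracle_mass) / oracle_mass, 1e-10)
  }

  # mirror symmetry for mirror-symmetric data on a symmetric grid
  sym <- make_track(c(-50, 50), c(0, 0))
  ud_sym <- kde_ud(sym, manual_bandwidth(40), grid)
  expect_equal(ud_sym$mass, ud_sym$mass[, 40:1], tolerance = 1e-12)

  expect_error(kde_ud(make_track(1000, 1000), manual_bandwidth(10), grid),
               "cover")
  lscv_bad <- bandwidth_spec("lscv", 10, converged = FALSE)
  expect_error(kde_ud(tr, lscv_bad, grid), "converge")
})

test_that("href oversmooths and LSCV undersmooths a two-cluster track", {
  set.seed(6)
  tr <- make_track(c(rnorm(60, 0, 8), rnorm(60, 600, 8)),
                   c(rnorm(60, 0, 8), rnorm(60, 0, 8)))
  grid <- make_reference_grid(tr, 10, 150)
  ud_href <- kde_ud(tr, href_bandwidth(tr), grid)
  bw_lscv <- lscv_bandwidth(tr)
  bw_lscv$converged <- TRUE
  ud_lscv <- kde_ud(tr, bw_lscv, grid)
  r_href <- isopleth_region(ud_href, 0.95)
  r_lscv <- isopleth_region(ud_lscv, 0.95)
  expect_lte(n_patches(r_href), n_patches(r_lscv))
  expect_gt(r_href$area_ha, r_lscv$area_ha)
})

test_that("halving a manual bandwidth never grows the 50% core", {
  for (seed in 1:3) {
    set.seed(seed)
    tr <- make_track(rnorm(50, sd = 50), rnorm(50, sd = 50))
    grid <- make_reference_grid(tr, 10, 200)
    a_wide <- isopleth_region(kde_ud(tr, manual_bandwidth(60), grid), 0.5)
    a_narrow <- isopleth_region(kde_ud(tr, manual_bandwidth(30), grid), 0.5)
    expect_lte(a_narrow$area_ha, a_wide$area_ha)
  }
})

test_that("a manual bandwidth can be matched to a target isopleth area", {
  set.seed(8)
  tr <- make_track(rnorm(60, sd = 100), rnorm(60, sd = 100))
  grid <- make_reference_grid(tr, 10, 400)
  bw <- match_bandwidth_to_area(tr, grid, target_area_ha = 30, level = 0.95)
  got <- isopleth_region(kde_ud(tr, bw, grid), 0.95)$area_ha
  expect_lt(abs(got - 30) / 30, 0.1)
})
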