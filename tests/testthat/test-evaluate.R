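test_that("AUC handles separation, ties and the printed pair example", {
  g <- grid_spec(0, 0, 10, 2, 2)
  tr <- make_track(c(5, 15), c(5, 5))    # presence in cells (1,1), (1,2)

  perfect <- ud_raster(g, matrix(c(0.5, 0.5, 0, 0), 2, 2, byrow = TRUE))
  expect_equal(home_range_auc(perfect, tr), 1)

  flat <- ud_raster(g, matrix(0.25, 2, 2))
  expect_equal(home_range_auc(flat, tr), 0.5)

  # presence scores {0.9, 0.5}, absence {0.5, 0.1}:
  # 3 concordant pairs + 1 tie of 4 -> 0.875
  ud <- ud_raster(g, matrix(c(0.9, 0.5, 0.5, 0.1), 2, 2, byrow = TRUE) / 2)
  expect_equal(home_range_auc(ud, tr), 0.875)

  expect_error(home_range_auc(ud, make_track(c(5, 15, 25, 5), c(5, 5, 5, 15))),
               "outside|absence")
})

test_that("AUC equals brute-force pair concordance on random instances", {
  set.seed(11)
  for (k in 1:5) {
    nr <- sample(5:12, 1)
    nc <- sample(5:12, 1)
    g <- grid_spec(0, 0, 10, nc, nr)
    m <- matrix(sample(c(0, 1, 2, 5), nr * nc, replace = TRUE) + 0.01,
                nr, nc)
    ud <- ud_raster(g, m)
    n_pres <- sample(3:8, 1)
    rows <- sample(nr, n_pres, replace = TRUE)
    cols <- sample(nc, n_pres, replace = TRUE)
    tr <- make_track((cols - 0.5) * 10, (rows - 0.5) * 10)
    pres <- matrix(FALSE, nr, nc)
    pres[cbind(rows, cols)] <- TRUE
    sp <- ud$mass[pres]
    sa <- ud$mass[!pres]
    pairs <- outer(sp, sa, function(p, a) (p > a) + 0.5 * (p == a))
    expect_equal(home_range_auc(ud, tr), mean(pairs))
  }
})

test_that("random score permutations give AUC centred on one half", {
  set.seed(12)
  g <- grid_spec(0, 0, 10, 20, 20)
  tr <- make_track(runif(30, 0, 200), runif(30, 0, 200))
  aucs <- numeric(500)
  base <- rexp(400) + 1e-6
  for (k in 1:500) {
    ud <- ud_raster(g, matrix(sample(base), 20, 20))
    aucs[k] <- home_range_auc(ud, tr)
  }
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("selection ratios follow Manly's definition", {
  g <- grid_spec(0, 0, 10, 10, 10)
  codes <- matrix(1L, 10, 10)
  codes[, 6:10] <- 2L
  hab <- structure(list(
    grid = g, codes = codes,
    legend = tibble::tibble(code = 1:2, habitat = c("forest", "field"),
                            target_fraction = c(0.5, 0.5))
  ), class = "habitat_raster")
  mk <- function(rows, cols) {
    structure(list(level = 0.5, grid = g,
                   cells = tibble::tibble(row = rows, col = cols,
                                          mass = 1 / length(rows))),
              class = "isopleth_region")
  }
  # used composition equals available composition -> all ratios 1
  avail <- mk(rep(1:2, each = 10), rep(1:10, 2))
  used <- mk(rep(1, 10), 1:10)
  st <- selection_ratios(used, avail, hab)
  expect_equal(st$w, c(1, 1))
  expect_equal(st$classification, rep("proportional", 2))

  # u = 0.4, a = 0.2 -> w = 2, selected (used contained in available)
  avail2 <- mk(rep(1:2, each = 5), c(1:3, 6, 7, 1:5))  # a_field = 0.2
  used2 <- mk(rep(1, 5), c(1, 2, 3, 6, 7))             # u_field = 0.4
  st2 <- selection_ratios(used2, avail2, hab)
  expect_equal(st2$w[st2$habitat == "field"], 2)
  expect_equal(st2$classification[st2$habitat == "field"],
               "more than available")

  # habitat present in used but absent from available -> undefined
  avail3 <- mk(rep(1, 4), 1:4)
  used3 <- mk(c(1, 1), c(1, 6))
  expect_warning(st3 <- selection_ratios(used3, avail3, hab),
                 "not contained")
  expect_equal(st3$classification[st3$habitat == "field"], "undefined")
  expect_true(is.na(st3$w[st3$habitat == "field"]))

  # invariant to relabeling of habitat codes
  hab_swap <- hab
  hab_swap$codes <- 3L - hab$codes
  hab_swap$legend$code <- 2:1
  st_swap <- selection_ratios(used2, avail2, hab_swap)
  expect_equal(st_swap$w[match(st2$habitat, st_swap$habitat)], st2$w)
})

test_that("variance summaries recover habitat-linked activity", {
  # high-variance phase confined to habitat A, low phase to habitat B,
  # joined by a moderate-step transit (no teleport spike)
  set.seed(13)
  n <- 200
  x <- cumsum(c(rnorm(n, 0, sqrt(50)), rep(30, 20), rnorm(n, 0, sqrt(5))))
  y <- cumsum(c(rnorm(n, 0, sqrt(50)), rep(0, 20), rnorm(n, 0, sqrt(5))))
  tr <- make_track(x, y)
  prof <- dbbmm_variance_profile(tr)
  g <- make_reference_grid(tr, 50, 100)
  codes <- matrix(2L, g$n_rows, g$n_cols)
  xs <- rangebridge:::grid_centers_x(g)
  codes[, xs < (x[n] + x[n + 21]) / 2] <- 1L
  hab <- structure(list(
    grid = g, codes = codes,
    legend = tibble::tibble(code = 1:2, habitat = c("A", "B"),
                            target_fraction = c(0.5, 0.5))
  ), class = "habitat_raster")
  out <- variance_by_category(prof, tr, hab)
  habrows <- out[out$group_type == "habitat", ]
  expect_gt(habrows$mean_sigma2m[habrows$group == "A"],
            habrows$mean_sigma2m[habrows$group == "B"])

  # single habitat -> single habitat row
  hab1 <- hab
  hab1$codes[] <- 1L
  out1 <- variance_by_category(prof, tr, hab1)
  expect_equal(sum(out1$group_type == "habitat"), 1)
})

test_that("season means are homogeneous on a single-state track", {
  cfg <- sim_config(behavior_state("bm", 50, 1e9), schedule = c(8, 14, 20),
                    start = "2014-01-01", end = "2014-12-31", error_sd = 0,
                    cold_season_fixes_per_day = 3, seed = 14)
  sim <- simulate_track(cfg)
  prof <- dbbmm_variance_profile(sim$track)
  out <- variance_by_category(prof, sim$track, habitat = NULL)
  means <- out$mean_sigma2m
  # the window-averaged profile is autocorrelated over ~1 window length,
  # so scale the naive SEs by the effective sample size
  ses <- out$se_sigma2m * sqrt(11)
  for (i in 1:2) for (j in (i + 1):3) {
    expect_lt(abs(means[i] - means[j]), 2 * sqrt(ses[i]^2 + ses[j]^2))
  }
})

test_that("the estimator comparison emits all methods and qualitative orderings", {
  sim <- small_stopover_sim(seed = 2)
  grid <- make_reference_grid(sim$track, 25, 200)
  hab <- generate_habitat_map(c(forest = 0.6, open = 0.4), grid,
                              patchiness = 200, seed = 3)
  res <- compare_estimators(sim$track, grid = grid, habitat = hab,
                            scheme = NULL)
  methods <- unique(res$metrics$method)
  expect_setequal(methods, c("mcp", "kde_href", "kde_lscv", "kde_plugin",
                             "kde_h100", "bbmm", "dbbmm"))
  # MCP carries no AUC; bridge methods beat the reference-bandwidth KDE
  aucs <- res$metrics[res$metrics$metric == "auc", ]
  expect_false("mcp" %in% aucs$method)
  auc_of <- function(m) aucs$value[aucs$method == m]
  a50 <- res$metrics[res$metrics$metric == "area_ha" &
                       res$metrics$level == 0.5, ]
  area50 <- function(m) a50$value[a50$method == m]
  expect_gte(auc_of("dbbmm"), auc_of("kde_href"))
  expect_lt(area50("dbbmm"), area50("kde_href"))
  # selection table covers every UD-based method, never the MCP
  expect_false("mcp" %in% res$selection$method)
  expect_gte(length(unique(res$selection$method)), 5)
  sel <- res$selection
  sums <- dplyr::summarise(dplyr::group_by(sel, method),
                           u = sum(u), a = sum(a))
  expect_true(all(abs(sums$u - 1) < 1e-6))
  expect_true(all(abs(sums$a - 1) < 1e-6))
})

test_that("seasonal isopleths stay inside the buffered full-data range", {
  sim <- small_stopover_sim(seed = 5)
  grid <- make_reference_grid(sim$track, 25, 200)
  tr <- sim$track
  prof <- dbbmm_variance_profile(tr)
  ud_all <- compute_bb_ud(tr, prof, grid)
  r_all <- isopleth_region(ud_all, 0.99)
  mask <- rangebridge:::region_mask(r_all, grid)
  # expand by one cell (4-neighborhood dilation)
  pad <- rbind(FALSE, cbind(FALSE, mask, FALSE), FALSE)
  dil <- mask |
    pad[1:nrow(mask), 2:(ncol(mask) + 1)] |
    pad[3:(nrow(mask) + 2), 2:(ncol(mask) + 1)] |
    pad[2:(nrow(mask) + 1), 1:ncol(mask)] |
    pad[2:(nrow(mask) + 1), 3:(ncol(mask) + 2)]
  tr_season <- assign_seasons(tr)
  for (season in c("dry", "rainy")) {
    sub <- tr_season[tr_season$season == season, ]
    if (nrow(sub) < 20) next
    prof_s <- rangebridge:::seasonal_variance_profile(sub, dbbmm_config())
    r_s <- isopleth_region(compute_bb_ud(sub, prof_s, grid), 0.99)
    inside <- dil[cbind(r_s$cells$row, r_s$cells$col)]
    expect_gt(mean(inside), 0.95)
  }
})
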