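# Small deterministic fixtures used across the suite.

make_track <- function(x, y, dt_h = 1, error_sd = 0, animal_id = "a",
                       t0 = as.POSIXct("2014-06-01 00:00:00", tz = "UTC")) {
  n <- length(x)
  ts <- if (length(dt_h) == 1) t0 + (seq_len(n) - 1) * dt_h * 3600 else
    t0 + c(0, cumsum(dt_h)) * 3600
  as_track(tibble::tibble(
    animal_id = animal_id, timestamp = ts, x = x, y = y,
    error_sd = error_sd
  ))
}

# Single-state Brownian track with hourly fixes and no thinning.
bm_track <- function(sigma2m, n_fixes, error_sd = 0, seed = 1,
                     days = ceiling(n_fixes / 24) + 1) {
  cfg <- sim_config(
    behavior_state("bm", sigma2m, 1e9), schedule = 0:23,
    start = "2014-06-01", end = as.Date("2014-06-01") + days,
    error_sd = error_sd, cold_season_fixes_per_day = 24, seed = seed
  )
  sim <- simulate_track(cfg)
  list(track = dplyr::slice_head(sim$track, n = n_fixes),
       truth = dplyr::slice_head(sim$truth, n = n_fixes))
}

# Two-state track (variance ratio 10:1), hourly schedule, no noise.
two_state_track <- function(seed = 1, days = 46, s2 = c(5, 50),
                            dwell = 50, error_sd = 0) {
  cfg <- sim_config(
    list(behavior_state("lo", s2[1], dwell),
         behavior_state("hi", s2[2], dwell)),
    schedule = 0:23, start = "2014-06-01",
    end = as.Date("2014-06-01") + days,
    error_sd = error_sd, cold_season_fixes_per_day = 24, seed = seed
  )
  simulate_track(cfg)
}

# A shortened stopover fixture (same structure as the default study
# fixture, three months, one animal) for fast end-to-end tests.
small_stopover_sim <- function(seed = 1) {
  shelters <- cbind(x = c(100, 600, 1100), y = c(150, 800, 300))
  cfg <- sim_config(
    list(behavior_state("stopover", 2, 96),
         behavior_state("exploratory", 4000, 60)),
    start = "2014-06-01", end = "2014-09-01",
    shelter_sites = shelters, start_xy = c(400, 400),
    animal_id = "S1", seed = seed
  )
  simulate_track(cfg)
}

# Tiny hand-made UD on a 2x2 grid.
toy_ud_2x2 <- function(masses = c(0.4, 0.3, 0.2, 0.1)) {
  grid <- grid_spec(0, 0, 10, 2, 2)
  # masses in (row, col) order: (1,1) (1,2) (2,1) (2,2)
  ud_raster(grid, matrix(masses, 2, 2, byrow = TRUE))
}

# Independent brute-force convex hull area: a point is a hull vertex iff
# it is not strictly inside any triangle of three other points; vertices
# sorted by angle around the centroid, then shoelace.
brute_hull_area_m2 <- function(x, y) {
  pts <- unique(cbind(x, y))
  n <- nrow(pts)
  in_triangle <- function(p, a, b, c) {
    s1 <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    s2 <- (c[1] - b[1]) * (p[2] - b[2]) - (c[2] - b[2]) * (p[1] - b[1])
    s3 <- (a[1] - c[1]) * (p[2] - c[2]) - (a[2] - c[2]) * (p[1] - c[1])
    (s1 > 1e-12 & s2 > 1e-12 & s3 > 1e-12) |
      (s1 < -1e-12 & s2 < -1e-12 & s3 < -1e-12)
  }
  on_hull <- vapply(seq_len(n), function(i) {
    others <- setdiff(seq_len(n), i)
    combs <- utils::combn(others, 3)
    !any(vapply(seq_len(ncol(combs)), function(k) {
      in_triangle(pts[i, ], pts[combs[1, k], ], pts[combs[2, k], ],
                  pts[combs[3, k], ])
    }, logical(1)))
  }, logical(1))
  hp <- pts[on_hull, , drop = FALSE]
  ctr <- colMeans(hp)
  ord <- order(atan2(hp[, 2] - ctr[2], hp[, 1] - ctr[1]))
  hp <- hp[ord, , drop = FALSE]
  xh <- c(hp[, 1], hp[1, 1]); yh <- c(hp[, 2], hp[1, 2])
  m <- length(xh)
  abs(sum(xh[-m] * yh[-1] - xh[-1] * yh[-m])) / 2
}

# Count 4-connected components of a cell region.
n_patches <- function(region) {
  cells <- region$cells
  key <- paste(cells$row, cells$col)
  seen <- stats::setNames(rep(FALSE, nrow(cells)), key)
  patches <- 0
  for (k in key) {
    if (seen[[k]]) next
    patches <- patches + 1
    queue <- k
    while (length(queue) > 0) {
      cur <- queue[[1]]; queue <- queue[-1]
      if (seen[[cur]]) next
      seen[[cur]] <- TRUE
      rc <- as.integer(strsplit(cur, " ")[[1]])
      nb <- c(paste(rc[1] + 1, rc[2]), paste(rc[1] - 1, rc[2]),
              paste(rc[1], rc[2] + 1), paste(rc[1], rc[2] - 1))
      nb <- nb[nb %in% key]
      queue <- c(queue, nb[!vapply(nb, function(x) isTRUE(seen[[x]]),
                                   logical(1))])
    }
  }
  patches
}
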