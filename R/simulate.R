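#' Behavioral state for the track simulator
#'
#' The generator's movement law is state-switching Brownian motion: given
#' the current state, each coordinate increment over `dt` hours is Gaussian
#' with mean zero and variance `sigma2m * dt`. High-variance states produce
#' irregular, active paths; low-variance states produce stopovers.
#'
#' @param name State label.
#' @param sigma2m Brownian motion variance in m^2/hour (>= 0).
#' @param mean_dwell_h Mean state duration in hours (> 0), exponential dwell.
#' @return A list of class `behavior_state`.
#' @export
behavior_state <- function(name, sigma2m, mean_dwell_h) {
  if (sigma2m < 0) stop("sigma2m must be >= 0", call. = FALSE)
  if (mean_dwell_h <= 0) stop("mean_dwell_h must be > 0", call. = FALSE)
  structure(list(name = name, sigma2m = sigma2m,
                 mean_dwell_h = mean_dwell_h),
            class = "behavior_state")
}

#' Simulation configuration
#'
#' Emulates a VHF field protocol: fixes at set times of day, a reduced
#' number of daily fixes during the cold months, and isotropic Gaussian GPS
#' error per axis. State switches occur only at fix times (discretized
#' Markov chain with exponential dwell), so the true motion variance is
#' well-defined on every inter-fix interval.
#'
#' @param states List of [behavior_state()]s (at least one).
#' @param schedule Daily fix times in decimal hours, strictly increasing
#'   within the day. Default 06:30, 11:00, 16:00, 20:00.
#' @param start,end Tracking period (Date or parseable strings).
#' @param error_sd Per-axis GPS error SD in metres (default 5.5).
#' @param cold_season_fixes_per_day Fixes per day kept during cold months
#'   (default 2; the retained times are those closest to midday).
#' @param cold_months Months with the reduced schedule (default Dec-Feb).
#' @param shelter_sites Optional matrix/data frame of (x, y) stopover
#'   anchors. When given, entering an anchored state relocates the animal
#'   to the nearest site and holds it there for the duration of the state.
#' @param anchored_states Names of states to anchor; default: the state
#'   with the smallest `sigma2m` (only when `shelter_sites` is given).
#' @param start_xy Initial true position, default `c(0, 0)`.
#' @param cold_activity_factor Seasonal activity modulation (default 1 =
#'   none): during cold months the mean dwell of the lowest-variance
#'   state is multiplied by this factor and the dwell of every other
#'   state divided by it, emulating reduced cold-season activity (the
#'   same phenomenon that motivates the reduced winter fix schedule).
#' @param animal_id Label for the emitted track.
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(states,
                       schedule = c(6.5, 11, 16, 20),
                       start = "2014-03-01",
                       end = "2015-12-01",
                       error_sd = 5.5,
                       cold_season_fixes_per_day = 2,
                       cold_months = c(12, 1, 2),
                       shelter_sites = NULL,
                       anchored_states = NULL,
                       start_xy = c(0, 0),
                       cold_activity_factor = 1,
                       animal_id = "SIM1",
                       seed = 1L) {
  if (inherits(states, "behavior_state")) states <- list(states)
  if (length(states) < 1) stop("need at least one state", call. = FALSE)
  if (is.unsorted(schedule, strictly = TRUE)) {
    stop("schedule times must be strictly increasing within a day",
         call. = FALSE)
  }
  start <- as.Date(start)
  end <- as.Date(end)
  if (end < start) stop("end date before start date", call. = FALSE)
  if (!is.null(shelter_sites)) {
    shelter_sites <- as.matrix(as.data.frame(shelter_sites)[, 1:2])
    if (is.null(anchored_states)) {
      s2 <- vapply(states, function(s) s$sigma2m, numeric(1))
      anchored_states <- states[[which.min(s2)]]$name
    }
  }
  structure(
    list(states = states, schedule = schedule, start = start, end = end,
         error_sd = error_sd,
         cold_season_fixes_per_day = cold_season_fixes_per_day,
         cold_months = as.integer(cold_months),
         shelter_sites = shelter_sites,
         anchored_states = anchored_states,
         start_xy = start_xy,
         cold_activity_factor = cold_activity_factor,
         animal_id = animal_id,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Full fix-time grid (every schedule time on every day), POSIXct UTC.
schedule_times <- function(config) {
  days <- seq(config$start, config$end, by = "day")
  secs <- round(config$schedule * 3600)
  ts <- rep(as.POSIXct(paste(days, "00:00:00"), tz = "UTC"),
            each = length(secs)) + rep(secs, times = length(days))
  sort(ts)
}

# Times retained by the observation schedule (cold months reduced).
observed_times <- function(config) {
  ts <- schedule_times(config)
  k <- config$cold_season_fixes_per_day
  if (k >= length(config$schedule)) return(ts)
  keep_times <- sort(config$schedule[order(abs(config$schedule - 13))][seq_len(k)])
  months <- as.integer(format(ts, "%m", tz = "UTC"))
  hod <- as.numeric(difftime(ts, as.POSIXct(format(ts, "%Y-%m-%d", tz = "UTC"),
                                            tz = "UTC"), units = "hours"))
  cold <- months %in% config$cold_months
  ts[!cold | hod %in% keep_times]
}

#' Simulate a radio-tracking dataset with known ground truth
#'
#' Runs the state-switching Brownian motion at the full daily schedule,
#' then passes it through the observation model (cold-season thinning plus
#' GPS noise). Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list with `track` (observed track tibble, see [as_track()])
#'   and `truth` (tibble aligned row-by-row with the track: true positions,
#'   true state, and `true_sigma2m` of the interval starting at each fix,
#'   `NA` for the last fix).
#' @export
simulate_track <- function(config) {
  truth_full <- withr::with_seed(config$seed, simulate_truth_full(config))
  track <- withr::with_seed(config$seed + 1000003L,
                            apply_observation_model_(truth_full, config))
  truth <- attr(track, "truth")
  attr(track, "truth") <- NULL
  list(track = track, truth = truth)
}

# Internal: true path at every schedule time.
simulate_truth_full <- function(config) {
  ts <- schedule_times(config)
  n <- length(ts)
  s2 <- vapply(config$states, function(s) s$sigma2m, numeric(1))
  dwell <- vapply(config$states, function(s) s$mean_dwell_h, numeric(1))
  nms <- vapply(config$states, function(s) s$name, character(1))
  k <- length(s2)
  dt <- as.numeric(difftime(ts[-1], ts[-n], units = "hours"))

  state <- integer(n)
  state[1] <- sample.int(k, 1)
  caf <- config$cold_activity_factor %||% 1
  slow <- which.min(s2)
  cold <- as.integer(format(ts, "%m", tz = "UTC")) %in% config$cold_months
  dwell_at <- function(st, i) {
    if (caf == 1 || !cold[i]) return(dwell[st])
    if (st == slow) dwell[st] * caf else dwell[st] / caf
  }
  if (k > 1) {
    u <- stats::runif(n - 1)
    pick <- stats::runif(n - 1)
    for (i in seq_len(n - 1)) {
      p_switch <- 1 - exp(-dt[i] / dwell_at(state[i], i))
      if (u[i] < p_switch) {
        others <- setdiff(seq_len(k), state[i])
        state[i + 1] <- others[ceiling(pick[i] * length(others))]
      } else {
        state[i + 1] <- state[i]
      }
    }
  } else {
    state[] <- 1L
  }

  inc_x <- stats::rnorm(n - 1, 0, sqrt(s2[state[-n]] * dt))
  inc_y <- stats::rnorm(n - 1, 0, sqrt(s2[state[-n]] * dt))
  true_s2 <- s2[state[-n]]

  anchored <- nms %in% (config$anchored_states %||% character(0))
  if (!is.null(config$shelter_sites) && any(anchored)) {
    # anchored states hold position at the nearest shelter site
    x <- numeric(n); y <- numeric(n)
    x[1] <- config$start_xy[1]; y[1] <- config$start_xy[2]
    if (anchored[state[1]]) {
      j <- nearest_site(config$shelter_sites, x[1], y[1])
      x[1] <- config$shelter_sites[j, 1]; y[1] <- config$shelter_sites[j, 2]
    }
    for (i in seq_len(n - 1)) {
      if (anchored[state[i]]) {
        x[i + 1] <- x[i]; y[i + 1] <- y[i]
        true_s2[i] <- 0
      } else {
        x[i + 1] <- x[i] + inc_x[i]
        y[i + 1] <- y[i] + inc_y[i]
      }
      if (anchored[state[i + 1]] && !anchored[state[i]]) {
        j <- nearest_site(config$shelter_sites, x[i + 1], y[i + 1])
        x[i + 1] <- config$shelter_sites[j, 1]
        y[i + 1] <- config$shelter_sites[j, 2]
      }
    }
  } else {
    x <- config$start_xy[1] + c(0, cumsum(inc_x))
    y <- config$start_xy[2] + c(0, cumsum(inc_y))
  }

  tibble::tibble(
    animal_id = config$animal_id,
    timestamp = ts,
    x_true = x, y_true = y,
    state = nms[state],
    true_sigma2m = c(true_s2, NA_real_)
  )
}

nearest_site <- function(sites, x, y) {
  which.min((sites[, 1] - x)^2 + (sites[, 2] - y)^2)
}

#' Apply the observation model to a true path
#'
#' Samples the truth at the observation schedule (reduced to
#' `cold_season_fixes_per_day` fixes during cold months) and adds
#' independent Gaussian noise with SD `config$error_sd` per axis. The
#' emitted `error_sd` column equals `config$error_sd`.
#'
#' @param truth A truth tibble from [simulate_track()] internals (columns
#'   `animal_id`, `timestamp`, `x_true`, `y_true`, `state`, `true_sigma2m`).
#' @param config The [sim_config()].
#' @return An observed track tibble.
#' @export
apply_observation_model <- function(truth, config) {
  if (nrow(truth) == 0) stop("truth is empty", call. = FALSE)
  track <- withr::with_seed(config$seed + 1000003L,
                            apply_observation_model_(truth, config))
  attr(track, "truth") <- NULL
  track
}

apply_observation_model_ <- function(truth, config) {
  obs_ts <- observed_times(config)
  keep <- truth$timestamp %in% obs_ts
  sub <- truth[keep, , drop = FALSE]
  n <- nrow(sub)
  # true variance of each observed interval: time-weighted mean of the
  # underlying per-interval variances it spans
  if (n > 1) {
    full_ts <- as.numeric(truth$timestamp) / 3600
    full_s2 <- truth$true_sigma2m
    idx <- match(sub$timestamp, truth$timestamp)
    s2_obs <- vapply(seq_len(n - 1), function(i) {
      a <- idx[i]; b <- idx[i + 1]
      w <- diff(full_ts[a:b])
      sum(w * full_s2[a:(b - 1)]) / sum(w)
    }, numeric(1))
    sub$true_sigma2m <- c(s2_obs, NA_real_)
  }
  obs <- tibble::tibble(
    animal_id = sub$animal_id,
    timestamp = sub$timestamp,
    x = sub$x_true + stats::rnorm(n, 0, config$error_sd),
    y = sub$y_true + stats::rnorm(n, 0, config$error_sd),
    error_sd = config$error_sd
  )
  track <- as_track(obs, error_default = config$error_sd,
                    crs_note = "synthetic planar metric CRS")
  attr(track, "truth") <- sub
  track
}

#' Default two-animal study fixture
#'
#' Two synthetic animals emulating the scale of the original field design:
#' one tracked 649 days and one 533 days at four fixes/day (two in
#' Dec-Feb), 5.5 m GPS error, alternating multi-day stopovers at shelter
#' sites with exploratory Brownian bouts. Stopovers have sigma2m =
#' 2 m^2/h; the exploratory variance differs by animal (25,000 and
#' 12,000 m^2/h) so that mean step lengths land near the field-reported
#' few-hundred-metre scale for an adult and a juvenile; stopovers last
#' 108 h on average against 66 h exploratory bouts, so the animals spend
#' roughly half their time (slightly more) sheltering. Shelter sites are
#' scattered over roughly 3.5 x 3.5 km.
#'
#' @param seed Integer seed controlling both animals.
#' @return A list with `track` (both animals bound together), `truth`
#'   (aligned list by animal), and `shelters`.
#' @export
simulate_study_tracks <- function(seed = 1L) {
  shelters <- default_shelter_sites()
  states_adult <- list(
    behavior_state("stopover", sigma2m = 2, mean_dwell_h = 108),
    behavior_state("exploratory", sigma2m = 25000, mean_dwell_h = 66)
  )
  states_juv <- list(
    behavior_state("stopover", sigma2m = 2, mean_dwell_h = 108),
    behavior_state("exploratory", sigma2m = 12000, mean_dwell_h = 66)
  )
  cfg1 <- sim_config(
    states_adult, start = "2014-03-01", end = as.Date("2014-03-01") + 649,
    shelter_sites = shelters, start_xy = c(800, 900),
    cold_activity_factor = 3,
    animal_id = "SIM1", seed = seed * 13L + 1L
  )
  cfg2 <- sim_config(
    states_juv, start = "2014-07-15", end = as.Date("2014-07-15") + 533,
    shelter_sites = shelters, start_xy = c(1300, 600),
    cold_activity_factor = 3,
    animal_id = "SIM2", seed = seed * 13L + 2L
  )
  r1 <- simulate_track(cfg1)
  r2 <- simulate_track(cfg2)
  list(
    track = dplyr::bind_rows(r1$track, r2$track) |> as_track(),
    truth = list(SIM1 = r1$truth, SIM2 = r2$truth),
    shelters = shelters,
    configs = list(SIM1 = cfg1, SIM2 = cfg2)
  )
}

default_shelter_sites <- function() {
  cbind(
    x = c(200, 950, 1700, 2600, 3300, 500, 1900, 2900, 1200, 2300),
    y = c(400, 2100, 1000, 2900, 600, 1300, 2400, 1700, 3200, 300)
  )
}

#' Generate a patchy categorical habitat raster
#'
#' Threshold-of-smoothed-noise construction: white noise on the grid is
#' smoothed with a Gaussian kernel of the requested length scale and then
#' cut at the quantiles implied by the target fractions, so category
#' fractions match the targets up to discretization and the map is
#' spatially autocorrelated at the given scale. Deterministic under `seed`.
#'
#' @param categories Named numeric vector of target fractions (must sum
#'   to 1 within 1e-6), e.g. `c(DEF = 0.3, DDF = 0.25, ...)`.
#' @param grid A [grid_spec()].
#' @param patchiness Spatial autocorrelation length scale in metres.
#' @param seed Integer seed.
#' @return A list of class `habitat_raster` with `grid`, integer `codes`
#'   matrix (n_rows x n_cols) and a `legend` tibble (code, habitat, fraction).
#' @export
generate_habitat_map <- function(categories, grid, patchiness = 250,
                                 seed = 1L) {
  fr <- as.numeric(categories)
  if (any(fr <= 0)) stop("target fractions must be positive", call. = FALSE)
  if (abs(sum(fr) - 1) > 1e-6) {
    stop("target fractions must sum to 1 (within 1e-6)", call. = FALSE)
  }
  nms <- names(categories) %||% paste0("H", seq_along(fr))
  codes <- withr::with_seed(seed, {
    noise <- matrix(stats::rnorm(grid$n_rows * grid$n_cols),
                    grid$n_rows, grid$n_cols)
    if (length(fr) == 1) {
      matrix(1L, grid$n_rows, grid$n_cols)
    } else {
      sm <- smooth_gaussian(noise, patchiness / grid$cell_size)
      q <- stats::quantile(sm, probs = cumsum(fr)[-length(fr)], type = 1)
      matrix(findInterval(sm, q, left.open = TRUE) + 1L,
             grid$n_rows, grid$n_cols)
    }
  })
  structure(
    list(grid = grid, codes = codes,
         legend = tibble::tibble(code = seq_along(fr), habitat = nms,
                                 target_fraction = fr)),
    class = "habitat_raster"
  )
}

# Separable Gaussian smoothing; sd in cell units.
smooth_gaussian <- function(m, sd_cells) {
  if (sd_cells <= 0) return(m)
  kern <- function(n) {
    idx <- seq_len(n)
    K <- outer(idx, idx, function(i, j) stats::dnorm(i - j, sd = sd_cells))
    K / rowSums(K)
  }
  kern(nrow(m)) %*% m %*% t(kern(ncol(m)))
}

#' Default habitat composition for synthetic landscapes
#'
#' Fractions loosely mirroring a forest reserve within an agricultural
#' matrix: evergreen forest, dipterocarp forest, plantations, agriculture,
#' settlements and water.
#' @return Named numeric vector summing to 1.
#' @export
default_habitat_fractions <- function() {
  c(DEF = 0.30, DDF = 0.25, plantation = 0.15, agriculture = 0.20,
    settlement = 0.07, water = 0.03)
}

#' @export
print.habitat_raster <- function(x, ...) {
  cat(sprintf("<habitat_raster> %d x %d cells (%g m), %d categories\n",
              x$grid$n_cols, x$grid$n_rows, x$grid$cell_size,
              nrow(x$legend)))
  invisible(x)
}
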