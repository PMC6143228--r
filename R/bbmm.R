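#' Leave-one-out negative log-likelihood of the Brownian motion variance
#'
#' The motion variance sigma2m is estimated by leaving out alternating
#' interior fixes: each selected fix i is predicted by the Brownian bridge
#' between its neighbours, with per-axis variance
#' `v_i = (t_{i+1}-t_{i-1}) * a_i * (1-a_i) * sigma2m
#'        + (1-a_i)^2 * delta_{i-1}^2 + a_i^2 * delta_{i+1}^2 + delta_i^2`
#' where `a_i` is the fractional time position of fix i between its
#' neighbours. The predicted fix's own GPS error `delta_i^2` is added
#' because the observation is the bridge value plus independent location
#' noise. The default index set is every second interior fix, so no fix is
#' both predictor and predictand.
#'
#' @param track A single-animal track tibble (>= 3 fixes).
#' @param sigma2m Motion variance in m^2/hour (>= 0).
#' @param index_set Integer indices of interior fixes to leave out;
#'   default `seq(2, n - 1, by = 2)`.
#' @return The negative log-likelihood (scalar); `Inf` if any term has
#'   zero variance with a nonzero deviation.
#' @export
loo_neg_log_likelihood <- function(track, sigma2m, index_set = NULL) {
  n <- nrow(track)
  if (n < 3) stop("need at least 3 relocations", call. = FALSE)
  if (sigma2m < 0) stop("sigma2m must be >= 0", call. = FALSE)
  index_set <- index_set %||% seq(2, n - 1, by = 2)
  if (any(index_set < 2 | index_set > n - 1)) {
    stop("index_set must contain interior indices only", call. = FALSE)
  }
  tt <- bridge_terms(track)
  loo_nll(tt, sigma2m, match(index_set, tt$i))
}

# Precomputed per-interior-fix likelihood terms: v = a * sigma2m + b,
# squared deviation d2. Times in hours.
bridge_terms <- function(track) {
  n <- nrow(track)
  t_h <- as.numeric(track$timestamp) / 3600
  i <- 2:(n - 1)
  a_idx <- i - 1
  b_idx <- i + 1
  alpha <- (t_h[i] - t_h[a_idx]) / (t_h[b_idx] - t_h[a_idx])
  Ttot <- t_h[b_idx] - t_h[a_idx]
  mu_x <- track$x[a_idx] + alpha * (track$x[b_idx] - track$x[a_idx])
  mu_y <- track$y[a_idx] + alpha * (track$y[b_idx] - track$y[a_idx])
  d <- track$error_sd %||% rep(0, n)
  list(
    i = i,
    a = Ttot * alpha * (1 - alpha),
    b = (1 - alpha)^2 * d[a_idx]^2 + alpha^2 * d[b_idx]^2 + d[i]^2,
    d2 = (track$x[i] - mu_x)^2 + (track$y[i] - mu_y)^2
  )
}

# nll over a subset of term rows (positions into the term table).
loo_nll <- function(tt, sigma2m, rows) {
  v <- tt$a[rows] * sigma2m + tt$b[rows]
  d2 <- tt$d2[rows]
  if (any(v == 0 & d2 > 0)) return(Inf)
  sum(log(2 * pi * v) + d2 / (2 * v))
}

# Minimize loo_nll over log(sigma2m) within a bracket.
fit_sigma2m <- function(tt, rows, bracket, tol = 1e-6) {
  opt <- stats::optimize(function(l) loo_nll(tt, exp(l), rows),
                         interval = log(bracket), tol = tol)
  s2 <- exp(opt$minimum)
  log_range <- diff(log(bracket))
  boundary <- (opt$minimum - log(bracket[1]) < 1e-4 * log_range) ||
    (log(bracket[2]) - opt$minimum < 1e-4 * log_range)
  list(sigma2m = s2, nll = opt$objective, boundary = boundary)
}

default_bracket <- function(track) {
  step2 <- max(diff(track$x)^2 + diff(track$y)^2)
  min_lag <- min(lag_hours(track))
  hi <- max(10 * step2 / min_lag, 1e-6)
  c(1e-8, hi)
}

#' Maximum-likelihood Brownian motion variance (constant along the path)
#'
#' Minimizes [loo_neg_log_likelihood()] by bounded derivative-free search
#' on the log scale. This is the BBMM assumption: one sigma2m for the
#' whole track.
#'
#' @param track A single-animal track tibble (>= 3 fixes).
#' @param bracket Search interval `(lo, hi)` in m^2/hour; default
#'   `c(1e-8, 10 * max(step)^2 / min(lag))`.
#' @return The estimate (m^2/hour) with attributes `boundary` (TRUE when
#'   the optimum sat at a bracket end, e.g. motion variance ~ 0) and `nll`.
#' @export
estimate_sigma2m <- function(track, bracket = NULL) {
  n <- nrow(track)
  if (n < 3) stop("need at least 3 relocations", call. = FALSE)
  bracket <- bracket %||% default_bracket(track)
  tt <- bridge_terms(track)
  rows <- match(seq(2, n - 1, by = 2), tt$i)
  fit <- fit_sigma2m(tt, rows, bracket)
  structure(fit$sigma2m, boundary = fit$boundary, nll = fit$nll)
}

#' Configuration for the dynamic (windowed) variance estimation
#'
#' @param window Number of consecutive fixes per sliding window
#'   (default 11, conventionally an odd count).
#' @param margin Minimum number of fixes on each side of a candidate
#'   behavioral breakpoint (default 3).
#' @param criterion Information criterion for the one-sigma vs breakpoint
#'   comparison; only `"BIC"` is implemented.
#' @param max_lag_h Optional threshold (hours): intervals longer than this
#'   are excluded from UD integration (default `NULL` = bridge everything).
#' @return A list of class `dbbmm_config`.
#' @export
dbbmm_config <- function(window = 11, margin = 3, criterion = "BIC",
                         max_lag_h = NULL) {
  if (margin < 1) stop("margin must be >= 1", call. = FALSE)
  if (window < 2 * margin + 1) {
    stop("window must be >= 2 * margin + 1", call. = FALSE)
  }
  if (!identical(criterion, "BIC")) {
    stop("only the BIC criterion is implemented", call. = FALSE)
  }
  structure(list(window = as.integer(window), margin = as.integer(margin),
                 criterion = criterion, max_lag_h = max_lag_h),
            class = "dbbmm_config")
}

#' Sliding-window variance profile with change-point model selection
#'
#' Slides a window of `window` consecutive fixes along the track one fix
#' at a time. Within each window the constant-variance model is compared
#' by BIC against every single-breakpoint model that leaves at least
#' `margin` fixes on both sides (a candidate additionally needs at least
#' 3 fixes per part to support the leave-one-out likelihood; when no
#' candidate is feasible the window keeps one variance). Under a
#' breakpoint the two variances are estimated separately on the two
#' sub-tracks, so no leave-one-out bridge straddles the candidate change;
#' both models are then scored by BIC on the same full window term set,
#' keeping the comparison on identical data.
#' Every non-margin fix of the window records
#' the variance of its part under the winning model; the final
#' per-location value is the mean over all windows that scored the fix,
#' with the track's unscored leading/trailing margins inheriting the
#' nearest scored value. Per-interval variance is the mean of its two
#' endpoint values.
#'
#' @param track A single-animal track tibble with at least `window` fixes.
#' @param config A [dbbmm_config()].
#' @return A tibble of class `variance_profile`: `animal_id`, `timestamp`,
#'   `sigma2m` (per location) and `sigma2m_interval` (interval starting at
#'   each fix; `NA` on the last row), with `window`/`margin` attributes.
#' @export
dbbmm_variance_profile <- function(track, config = dbbmm_config()) {
  w <- config$window
  m <- config$margin
  n <- nrow(track)
  if (n < w) {
    stop("track (", n, " fixes) is shorter than the window (", w, ")",
         call. = FALSE)
  }
  tt <- bridge_terms(track)
  bracket <- default_bracket(track)

  acc_sum <- numeric(n)
  acc_cnt <- integer(n)
  min_part <- max(m, 3L)

  for (s in seq_len(n - w + 1)) {
    # local leave-one-out indices 2, 4, ... within the window
    loc_idx <- seq(2, w - 1, by = 2)
    glob_idx <- s + loc_idx - 1
    rows <- glob_idx - 1       # term table rows are interior fixes 2..n-1
    n_terms <- length(rows)

    fit0 <- fit_sigma2m(tt, rows, bracket)
    bic0 <- 2 * fit0$nll + log(n_terms)

    best <- list(bic = bic0, breaks = FALSE)
    for (j in seq_len(w - 1)) {               # split after local fix j
      if (j < min_part || (w - j) < min_part) next
      # each part's variance is fit on its own sub-track, so no
      # leave-one-out bridge straddles the candidate change; the BIC then
      # scores BOTH models on the full window term set (same data), each
      # term under the variance of the part holding its left-out fix
      left_est <- seq(2, j - 1, by = 2)
      right_est <- seq(j + 2, w - 1, by = 2)
      if (length(left_est) < 1 || length(right_est) < 1) next
      fl <- fit_sigma2m(tt, s + left_est - 2, bracket)
      fr <- fit_sigma2m(tt, s + right_est - 2, bracket)
      nll_b <- loo_nll(tt, fl$sigma2m, rows[loc_idx <= j]) +
        loo_nll(tt, fr$sigma2m, rows[loc_idx > j])
      bic_b <- 2 * nll_b + 2 * log(n_terms)
      if (bic_b < best$bic - 1e-9) {
        best <- list(bic = bic_b, breaks = TRUE, j = j,
                     s2_left = fl$sigma2m, s2_right = fr$sigma2m)
      }
    }

    score_pos <- (m + 1):(w - m)              # non-margin local positions
    vals <- if (!best$breaks) {
      rep(fit0$sigma2m, length(score_pos))
    } else {
      ifelse(score_pos <= best$j, best$s2_left, best$s2_right)
    }
    gp <- s + score_pos - 1
    acc_sum[gp] <- acc_sum[gp] + vals
    acc_cnt[gp] <- acc_cnt[gp] + 1L
  }

  sigma_loc <- ifelse(acc_cnt > 0, acc_sum / acc_cnt, NA_real_)
  scored <- which(acc_cnt > 0)
  if (length(scored) == 0) stop("no fixes were scored", call. = FALSE)
  sigma_loc[seq_len(min(scored) - 1)] <- sigma_loc[min(scored)]
  if (max(scored) < n) sigma_loc[(max(scored) + 1):n] <- sigma_loc[max(scored)]

  sigma_int <- (sigma_loc[-n] + sigma_loc[-1]) / 2
  out <- tibble::tibble(
    animal_id = track$animal_id,
    timestamp = track$timestamp,
    sigma2m = sigma_loc,
    sigma2m_interval = c(sigma_int, NA_real_)
  )
  class(out) <- c("variance_profile", class(tibble::tibble()))
  attr(out, "window") <- w
  attr(out, "margin") <- m
  out
}

#' Brownian bridge transition density
#'
#' Density (per m^2) of the animal's position at fractional time `alpha`
#' along the bridge between `start` and `end`, an isotropic bivariate
#' normal with mean `start + alpha * (end - start)` and per-axis variance
#' `s(alpha) = T * alpha * (1 - alpha) * sigma2m
#'             + (1 - alpha)^2 * delta_start^2 + alpha^2 * delta_end^2`.
#' When `s(alpha) = 0` the bridge degenerates to a point mass: the density
#' is 0 away from the mean and `Inf` at it (sentinel convention).
#'
#' @param T Time lag between the two fixes in hours.
#' @param alpha Position along the bridge in `[0, 1]`.
#' @param sigma2m Motion variance in m^2/hour.
#' @param delta_start,delta_end Endpoint location-error SDs (m).
#' @param start,end,at Length-2 `(x, y)` vectors in metres.
#' @return Density in 1/m^2.
#' @export
bridge_density <- function(T, alpha, sigma2m, delta_start, delta_end,
                           start, end, at) {
  stopifnot(T > 0, alpha >= 0, alpha <= 1, sigma2m >= 0)
  s <- T * alpha * (1 - alpha) * sigma2m +
    (1 - alpha)^2 * delta_start^2 + alpha^2 * delta_end^2
  mu <- start + alpha * (end - start)
  d2 <- sum((at - mu)^2)
  if (s == 0) {
    return(if (d2 == 0) Inf else 0)
  }
  exp(-d2 / (2 * s)) / (2 * pi * s)
}

#' Brownian bridge utilization distribution (BBMM / dBBMM)
#'
#' Integrates the bridge density over each inter-fix interval with
#' `n_alpha` equally spaced nodes (trapezoid weights), weights each
#' interval by its duration, sums over intervals, converts to cell masses
#' and normalizes to one. A constant `sigma2m` gives the BBMM; a
#' [dbbmm_variance_profile()] gives the dBBMM. Bridge evaluation is
#' truncated beyond 4.5 SDs of each node's mean (error < 1e-5 of the
#' node's mass).
#'
#' @param track A single-animal track tibble (>= 2 fixes).
#' @param profile Either a single motion variance (m^2/hour) or a
#'   `variance_profile` aligned with the track.
#' @param grid A [grid_spec()] covering the track.
#' @param n_alpha Number of quadrature nodes per interval (default 21).
#' @param max_lag_h Intervals longer than this (hours) are skipped
#'   (default `NULL`: all intervals bridged).
#' @return A [ud_raster()].
#' @export
compute_bb_ud <- function(track, profile, grid, n_alpha = 21,
                          max_lag_h = NULL) {
  n <- nrow(track)
  if (n < 2) stop("need at least 2 relocations", call. = FALSE)
  if (!grid_covers(grid, track$x, track$y)) {
    stop("grid does not cover the track; enlarge the extent/buffer",
         call. = FALSE)
  }
  if (inherits(profile, "variance_profile") ||
      (is.data.frame(profile) && "sigma2m_interval" %in% names(profile))) {
    if (nrow(profile) != n) {
      stop("variance profile is not aligned with the track", call. = FALSE)
    }
    s2_int <- profile$sigma2m_interval[-n]
  } else if (is.numeric(profile) && length(profile) == 1) {
    s2_int <- rep(as.numeric(profile), n - 1)
  } else {
    stop("`profile` must be a scalar sigma2m or a variance_profile",
         call. = FALSE)
  }

  lags <- lag_hours(track)
  keep <- if (is.null(max_lag_h)) rep(TRUE, n - 1) else lags <= max_lag_h
  if (!any(keep)) stop("no intervals left after max_lag_h filtering",
                       call. = FALSE)

  xs <- grid_centers_x(grid)
  ys <- grid_centers_y(grid)
  dens <- matrix(0, grid$n_rows, grid$n_cols)
  alphas <- seq(0, 1, length.out = n_alpha)
  wts <- c(0.5, rep(1, n_alpha - 2), 0.5) / (n_alpha - 1)
  delta <- track$error_sd %||% rep(0, n)

  for (i in which(keep)) {
    T_i <- lags[i]
    for (k in seq_len(n_alpha)) {
      a <- alphas[k]
      s <- T_i * a * (1 - a) * s2_int[i] +
        (1 - a)^2 * delta[i]^2 + a^2 * delta[i + 1]^2
      mu_x <- track$x[i] + a * (track$x[i + 1] - track$x[i])
      mu_y <- track$y[i] + a * (track$y[i + 1] - track$y[i])
      wgt <- T_i * wts[k]
      if (s == 0) {
        cell <- point_to_cell(grid, mu_x, mu_y)
        if (!is.na(cell$row)) {
          dens[cell$row, cell$col] <- dens[cell$row, cell$col] +
            wgt / grid$cell_size^2
        }
        next
      }
      sd <- sqrt(s)
      r <- 4.5 * sd
      cols <- which(xs >= mu_x - r & xs <= mu_x + r)
      rows <- which(ys >= mu_y - r & ys <= mu_y + r)
      if (length(cols) == 0 || length(rows) == 0) next
      gx <- stats::dnorm(xs[cols], mu_x, sd)
      gy <- stats::dnorm(ys[rows], mu_y, sd)
      dens[rows, cols] <- dens[rows, cols] + wgt * tcrossprod(gy, gx)
    }
  }
  ud_raster(grid, dens * grid$cell_size^2)
}
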