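#' AUC of a utilization distribution against the observed relocations
#'
#' Pixel-classification goodness of fit: presence cells are the grid cells
#' containing at least one relocation (a cell with five fixes counts
#' once), pseudo-absence cells are all other cells of the reference grid,
#' and the score of a cell is its UD mass. The AUC is the Mann-Whitney
#' statistic of presence vs absence scores, with ties counted as half —
#' the probability that a random presence cell outranks a random absence
#' cell. Because absences are the remaining grid, the value depends on the
#' shared grid extent: only compare AUCs computed on the same grid.
#'
#' @param ud A [ud_raster()].
#' @param track The relocations the UD was estimated from; all must fall
#'   inside the grid.
#' @return The AUC in `[0, 1]`.
#' @export
home_range_auc <- function(ud, track) {
  grid <- ud$grid
  cells <- point_to_cell(grid, track$x, track$y)
  if (anyNA(cells$row)) {
    stop("some relocations fall outside the UD grid", call. = FALSE)
  }
  presence <- matrix(FALSE, grid$n_rows, grid$n_cols)
  presence[cbind(cells$row, cells$col)] <- TRUE
  n1 <- sum(presence)
  n0 <- length(presence) - n1
  if (n1 == 0 || n0 == 0) {
    stop("need both presence and absence cells for AUC", call. = FALSE)
  }
  scores <- as.numeric(ud$mass)
  r <- rank(scores)                       # average ranks = half-tie counting
  (sum(r[as.logical(presence)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Manly selection ratios from used and available regions
#'
#' Compares habitat composition of a used region (conventionally the 50%
#' core isopleth) against an available region (the 99% isopleth):
#' `u_i` and `a_i` are cell-count proportions of habitat i within the
#' respective regions and `w_i = u_i / a_i`. A ratio of 1 means use in
#' proportion to availability, > 1 selection, < 1 avoidance. A habitat
#' used but absent from the available region gets classification
#' `"undefined"` and a flagged, infinite-by-convention `NA` ratio.
#'
#' @param used,available `isopleth_region`s on the habitat's grid.
#' @param habitat A `habitat_raster` (see [generate_habitat_map()]).
#' @return A tibble of class `selection_table`: `habitat`, `code`, `u`,
#'   `a`, `w`, `classification`.
#' @export
selection_ratios <- function(used, available, habitat) {
  if (!same_grid(used$grid, habitat$grid) ||
      !same_grid(available$grid, habitat$grid)) {
    stop("regions and habitat raster must share one grid", call. = FALSE)
  }
  if (nrow(used$cells) == 0 || nrow(available$cells) == 0) {
    stop("empty region", call. = FALSE)
  }
  ku <- paste(used$cells$row, used$cells$col)
  ka <- paste(available$cells$row, available$cells$col)
  if (!all(ku %in% ka)) {
    warning("used region is not contained in the available region",
            call. = FALSE)
  }
  codes_u <- habitat$codes[cbind(used$cells$row, used$cells$col)]
  codes_a <- habitat$codes[cbind(available$cells$row, available$cells$col)]
  out <- habitat$legend[, c("code", "habitat")]
  out$u <- as.numeric(table(factor(codes_u, levels = out$code))) /
    length(codes_u)
  out$a <- as.numeric(table(factor(codes_a, levels = out$code))) /
    length(codes_a)
  out$w <- ifelse(out$a > 0, out$u / out$a,
                  ifelse(out$u > 0, NA_real_, NA_real_))
  out$classification <- dplyr::case_when(
    out$a == 0 & out$u > 0 ~ "undefined",
    out$a == 0 & out$u == 0 ~ "absent",
    abs(out$w - 1) < 1e-9 ~ "proportional",
    out$w > 1 ~ "more than available",
    TRUE ~ "less than available"
  )
  out <- out[, c("habitat", "code", "u", "a", "w", "classification")]
  class(out) <- c("selection_table", class(tibble::tibble()))
  out
}

#' Motion variance summarized by habitat and by season
#'
#' Assigns each fix the habitat of its containing cell (fixes outside the
#' raster are counted under `"unknown"`) and its season label, then
#' summarizes the per-location motion variance: mean, standard error and
#' n per habitat and per season.
#'
#' @param profile A [dbbmm_variance_profile()] aligned with `track`.
#' @param track The single-animal track.
#' @param habitat A `habitat_raster`, or `NULL` to skip the habitat split.
#' @param scheme A [season_scheme()].
#' @return A tibble with `group_type` ("habitat"/"season"), `group`,
#'   `mean_sigma2m`, `se_sigma2m`, `n`.
#' @export
variance_by_category <- function(profile, track, habitat = NULL,
                                 scheme = season_scheme()) {
  if (nrow(profile) != nrow(track)) {
    stop("profile is not aligned with the track", call. = FALSE)
  }
  d <- tibble::tibble(sigma2m = profile$sigma2m)
  d$season <- as.character(assign_seasons(track, scheme)$season)
  if (!is.null(habitat)) {
    cells <- point_to_cell(habitat$grid, track$x, track$y)
    code <- ifelse(is.na(cells$row), NA_integer_,
                   habitat$codes[cbind(cells$row, cells$col)])
    d$habitat <- ifelse(
      is.na(code), "unknown",
      habitat$legend$habitat[match(code, habitat$legend$code)]
    )
  }
  summarize_group <- function(d, var) {
    d |>
      dplyr::group_by(group = .data[[var]]) |>
      dplyr::summarise(
        mean_sigma2m = mean(.data$sigma2m),
        se_sigma2m = stats::sd(.data$sigma2m) / sqrt(dplyr::n()),
        n = dplyr::n(), .groups = "drop"
      ) |>
      dplyr::mutate(group_type = var, .before = 1)
  }
  out <- summarize_group(d, "season")
  if (!is.null(habitat)) out <- dplyr::bind_rows(out, summarize_group(d, "habitat"))
  out
}

#' Run and score every home-range estimator on a shared grid
#'
#' Runs, per animal, the percent MCP, fixed KDE under the four bandwidth
#' selectors (href, LSCV, plug-in, manual h100), the BBMM and the dBBMM —
#' all on the same reference grid — and assembles the comparison table:
#' AUC (MCP excluded by construction; a non-converged LSCV is excluded
#' too and flagged), isopleth areas and complexities at the requested
#' levels, per-season areas (seasonal motion variance refit per
#' season-contiguous block), and, when a habitat raster is given, Manly
#' selection ratios (used = lowest level, available = highest level).
#' Estimator failures are recorded as flagged rows, not raised.
#'
#' @param track A track tibble with one or more animals.
#' @param grid A [grid_spec()]; default built from the track with the
#'   given cell size and buffer.
#' @param habitat Optional `habitat_raster` on the same grid.
#' @param levels Isopleth levels (default 0.50, 0.95, 0.99).
#' @param mcp_percent Percent for the MCP (default 95).
#' @param h_manual Manual KDE bandwidth in metres (default 100).
#' @param config A [dbbmm_config()] (window 11, margin 3 by default).
#' @param scheme A [season_scheme()]; set `NULL` to skip seasonal reruns.
#' @param cell_size,buffer Used only when `grid` is `NULL`.
#' @return A list of class `hr_evaluation` with tibbles `metrics`
#'   (animal, method, season, metric, level, value, flag), `selection`
#'   and `flags`.
#' @export
compare_estimators <- function(track, grid = NULL, habitat = NULL,
                               levels = c(0.50, 0.95, 0.99),
                               mcp_percent = 95, h_manual = 100,
                               config = dbbmm_config(),
                               scheme = season_scheme(),
                               cell_size = 25, buffer = 250) {
  grid <- grid %||% make_reference_grid(track, cell_size, buffer)
  animals <- split_by_animal(track)
  rows <- list()
  sel_rows <- list()
  flags <- list()
  note <- function(animal, method, msg) {
    flags[[length(flags) + 1]] <<- tibble::tibble(
      animal_id = animal, method = method, flag = msg
    )
  }
  add <- function(animal, method, season, metric, level, value) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      animal_id = animal, method = method, season = season,
      metric = metric, level = level, value = value
    )
  }

  for (id in names(animals)) {
    tr <- animals[[id]]

    # --- MCP: geometry only (no UD, no AUC, no selection) ---------------
    for (lv in levels) {
      res <- try(percent_mcp(tr, percent = lv * 100), silent = TRUE)
      if (inherits(res, "try-error")) {
        note(id, "mcp", paste0("MCP ", lv * 100, "% failed"))
        next
      }
      add(id, "mcp", "all", "area_ha", lv, res$area_ha)
      if (lv * 100 == mcp_percent) {
        add(id, "mcp", "all", "complexity", lv,
            res$perimeter_m / res$area_ha)
      }
    }

    # --- UD-based methods ----------------------------------------------
    uds <- list()
    bws <- list(
      kde_href = function() href_bandwidth(tr),
      kde_lscv = function() lscv_bandwidth(tr),
      kde_plugin = function() plugin_bandwidth(tr),
      kde_h100 = function() manual_bandwidth(h_manual)
    )
    lscv_converged <- TRUE
    for (method in names(bws)) {
      bw <- try(bws[[method]](), silent = TRUE)
      if (inherits(bw, "try-error")) {
        note(id, method, "bandwidth selection failed")
        next
      }
      if (method == "kde_lscv" && !bw$converged) {
        lscv_converged <- FALSE
        note(id, "kde_lscv",
             "LSCV did not converge (boundary minimizer); UD built from the boundary bandwidth, excluded from AUC")
        bw$converged <- TRUE  # build the UD anyway, mirroring field practice
      }
      uds[[method]] <- try(kde_ud(tr, bw, grid), silent = TRUE)
    }

    prof <- try(dbbmm_variance_profile(tr, config), silent = TRUE)
    s2_const <- try(estimate_sigma2m(tr), silent = TRUE)
    if (!inherits(s2_const, "try-error")) {
      uds$bbmm <- try(compute_bb_ud(tr, as.numeric(s2_const), grid,
                                    max_lag_h = config$max_lag_h),
                      silent = TRUE)
      if (isTRUE(attr(s2_const, "boundary"))) {
        note(id, "bbmm", "sigma2m estimate at bracket boundary")
      }
    } else {
      note(id, "bbmm", "sigma2m estimation failed")
    }
    if (!inherits(prof, "try-error")) {
      uds$dbbmm <- try(compute_bb_ud(tr, prof, grid,
                                     max_lag_h = config$max_lag_h),
                       silent = TRUE)
    } else {
      note(id, "dbbmm", "variance profile failed")
    }

    for (method in names(uds)) {
      ud <- uds[[method]]
      if (inherits(ud, "try-error")) {
        note(id, method, "UD computation failed")
        next
      }
      if (!(method == "kde_lscv" && !lscv_converged)) {
        auc <- try(home_range_auc(ud, tr), silent = TRUE)
        if (!inherits(auc, "try-error")) {
          add(id, method, "all", "auc", NA_real_, auc)
        }
      }
      regions <- list()
      for (lv in levels) {
        reg <- isopleth_region(ud, lv)
        regions[[as.character(lv)]] <- reg
        add(id, method, "all", "area_ha", lv, reg$area_ha)
        add(id, method, "all", "complexity", lv, reg$complexity)
      }
      if (!is.null(habitat)) {
        used <- regions[[as.character(min(levels))]]
        avail <- regions[[as.character(max(levels))]]
        st <- try(selection_ratios(used, avail, habitat), silent = TRUE)
        if (!inherits(st, "try-error")) {
          st$animal_id <- id
          st$method <- method
          sel_rows[[length(sel_rows) + 1]] <- st
        }
      }
    }

    # --- seasonal reruns ------------------------------------------------
    if (!is.null(scheme)) {
      tr_season <- assign_seasons(tr, scheme)
      for (season in names(scheme)) {
        sub <- tr_season[tr_season$season == season, , drop = FALSE]
        if (nrow(sub) < max(10, config$window)) {
          note(id, "all", paste0("season ", season,
                                 ": too few fixes, skipped"))
          next
        }
        season_uds <- list()
        for (method in names(bws)) {
          bw_s <- try(switch(method,
            kde_href = href_bandwidth(sub),
            kde_lscv = {
              b <- lscv_bandwidth(sub); b$converged <- TRUE; b
            },
            kde_plugin = plugin_bandwidth(sub),
            kde_h100 = manual_bandwidth(h_manual)
          ), silent = TRUE)
          if (!inherits(bw_s, "try-error")) {
            season_uds[[method]] <- try(kde_ud(sub, bw_s, grid),
                                        silent = TRUE)
          }
        }
        prof_s <- try(seasonal_variance_profile(sub, config),
                      silent = TRUE)
        s2_s <- try(estimate_sigma2m(sub), silent = TRUE)
        if (!inherits(s2_s, "try-error")) {
          season_uds$bbmm <- try(
            compute_bb_ud(sub, as.numeric(s2_s), grid,
                          max_lag_h = config$max_lag_h), silent = TRUE)
        }
        if (!inherits(prof_s, "try-error")) {
          season_uds$dbbmm <- try(
            compute_bb_ud(sub, prof_s, grid,
                          max_lag_h = config$max_lag_h), silent = TRUE)
        }
        for (method in names(season_uds)) {
          ud <- season_uds[[method]]
          if (inherits(ud, "try-error")) {
            note(id, method, paste0("season ", season, ": UD failed"))
            next
          }
          for (lv in levels) {
            reg <- isopleth_region(ud, lv)
            add(id, method, season, "area_ha", lv, reg$area_ha)
          }
        }
      }
    }
  }

  structure(
    list(
      metrics = dplyr::bind_rows(rows),
      selection = if (length(sel_rows)) dplyr::bind_rows(sel_rows) else
        tibble::tibble(),
      flags = if (length(flags)) dplyr::bind_rows(flags) else
        tibble::tibble(animal_id = character(), method = character(),
                       flag = character()),
      grid = grid, levels = levels
    ),
    class = "hr_evaluation"
  )
}

# Seasonal variance profile: the season's fixes form blocks separated by
# out-of-season gaps; sigma2m is refit per contiguous block (blocks
# shorter than the window inherit the constant-sigma fit of the block, or
# of the season when too short even for that).
seasonal_variance_profile <- function(track, config) {
  gap_h <- lag_hours(track)
  # a gap of more than 35 days cannot occur within one season's months
  block <- cumsum(c(0, gap_h > 35 * 24)) + 1
  n <- nrow(track)
  sigma_loc <- rep(NA_real_, n)
  for (b in unique(block)) {
    idx <- which(block == b)
    sub <- track[idx, , drop = FALSE]
    if (length(idx) >= config$window) {
      sigma_loc[idx] <- dbbmm_variance_profile(sub, config)$sigma2m
    } else if (length(idx) >= 3) {
      sigma_loc[idx] <- as.numeric(estimate_sigma2m(sub))
    }
  }
  if (anyNA(sigma_loc)) {
    fallback <- if (all(is.na(sigma_loc))) {
      as.numeric(estimate_sigma2m(track))
    } else {
      mean(sigma_loc, na.rm = TRUE)
    }
    sigma_loc[is.na(sigma_loc)] <- fallback
  }
  sigma_int <- (sigma_loc[-n] + sigma_loc[-1]) / 2
  out <- tibble::tibble(
    animal_id = track$animal_id, timestamp = track$timestamp,
    sigma2m = sigma_loc, sigma2m_interval = c(sigma_int, NA_real_)
  )
  class(out) <- c("variance_profile", class(tibble::tibble()))
  attr(out, "window") <- config$window
  attr(out, "margin") <- config$margin
  out
}

#' @export
print.hr_evaluation <- function(x, ...) {
  cat("<hr_evaluation>\n")
  aucs <- x$metrics[x$metrics$metric == "auc", ]
  if (nrow(aucs)) {
    cat("AUC by animal and method:\n")
    print(tidyr::pivot_wider(aucs[, c("animal_id", "method", "value")],
                             names_from = "method", values_from = "value"))
  }
  invisible(x)
}
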