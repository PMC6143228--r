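#' Validate and classify a relocation track
#'
#' A track is a tibble with one row per fix and columns `animal_id`
#' (character), `timestamp` (POSIXct, UTC, second resolution), `x`, `y`
#' (metres, projected CRS) and `error_sd` (per-axis GPS error SD in metres).
#' Coordinates must already be in a projected metric CRS; the package never
#' transforms coordinates itself, because every formula downstream is
#' Euclidean in metres.
#'
#' @param df A data frame with at least `animal_id`, `timestamp`, `x`, `y`.
#' @param error_default Value used to fill a missing `error_sd` column (m).
#' @param crs_note Optional free-text note recording the projection.
#' @return A tibble of class `rb_track`, sorted by animal and timestamp.
#' @export
as_track <- function(df, error_default = 5.5, crs_note = NULL) {
  required <- c("animal_id", "timestamp", "x", "y")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop(
      "track is missing required column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  out <- tibble::as_tibble(df)
  out$animal_id <- as.character(out$animal_id)
  if (!inherits(out$timestamp, "POSIXct")) {
    raw <- as.character(out$timestamp)
    ts <- as.POSIXct(strptime(raw, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
    ts[is.na(ts)] <- as.POSIXct(strptime(raw[is.na(ts)],
                                         "%Y-%m-%d %H:%M:%S", tz = "UTC"))
    ts[is.na(ts)] <- as.POSIXct(strptime(raw[is.na(ts)], "%Y-%m-%d",
                                         tz = "UTC"))
    bad <- which(is.na(ts) & !is.na(raw))
    if (length(bad) > 0) {
      stop("non-parseable timestamp at row(s): ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    out$timestamp <- ts
  }
  attr(out$timestamp, "tzone") <- "UTC"
  if (!"error_sd" %in% names(out)) out$error_sd <- error_default
  out$error_sd[is.na(out$error_sd)] <- error_default
  if (any(!is.finite(out$x)) || any(!is.finite(out$y))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  if (any(out$error_sd < 0)) stop("error_sd must be >= 0", call. = FALSE)

  ord <- order(out$animal_id, out$timestamp)
  if (!identical(ord, seq_len(nrow(out)))) {
    warning("relocations were not in time order; sorting", call. = FALSE)
    out <- out[ord, ]
  }
  dup <- duplicated(out[, c("animal_id", "timestamp")])
  if (any(dup)) {
    stop("duplicate timestamp(s) within an animal at row(s): ",
         paste(utils::head(which(dup), 5), collapse = ", "), call. = FALSE)
  }
  out <- out[, c("animal_id", "timestamp", "x", "y",
                 setdiff(names(out), c("animal_id", "timestamp", "x", "y")))]
  class(out) <- c("rb_track", class(tibble::tibble()))
  attr(out, "crs_note") <- crs_note %||% attr(df, "crs_note")
  out
}

#' Read a relocation track from CSV
#'
#' Expects the comma-separated dialect with a header row, columns
#' `animal_id,timestamp,x,y[,error_sd]`, ISO-8601 UTC timestamps and "."
#' decimal marks.
#'
#' @param path CSV file path.
#' @param error_default Per-axis location-error SD (m) used where the file
#'   has no `error_sd` column; defaults to 5.5 m, a typical handheld-GPS
#'   accuracy for ground-truthed VHF relocations.
#' @return A track tibble (see [as_track()]).
#' @export
read_track_csv <- function(path, error_default = 5.5) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_track(df, error_default = error_default)
}

#' Write a track to CSV (lossless round trip with [read_track_csv()])
#'
#' @param track A track tibble.
#' @param path Output path.
#' @export
write_track_csv <- function(track, path) {
  out <- as.data.frame(track)
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Season scheme: months assigned to named seasons
#'
#' The default follows the monsoonal classification used at the study scale:
#' cold December–February, dry March–June, rainy July–November. The month
#' sets must partition months 1–12.
#'
#' @param cold,dry,rainy Integer month vectors.
#' @return A named list of class `season_scheme`.
#' @export
season_scheme <- function(cold = c(12, 1, 2), dry = 3:6, rainy = 7:11) {
  scheme <- list(cold = as.integer(cold), dry = as.integer(dry),
                 rainy = as.integer(rainy))
  all_months <- sort(unname(unlist(scheme)))
  if (!identical(as.integer(all_months), 1:12)) {
    stop("season month sets must partition months 1-12 ",
         "(no overlap, no gaps)", call. = FALSE)
  }
  structure(scheme, class = "season_scheme")
}

#' Label each relocation with its season
#'
#' Season is a function of the timestamp's month only, so relabeling a copy
#' of the track shifted by whole years gives identical labels.
#'
#' @param track A track tibble.
#' @param scheme A [season_scheme()].
#' @return The track with an added `season` factor column.
#' @export
assign_seasons <- function(track, scheme = season_scheme()) {
  if (!inherits(scheme, "season_scheme")) scheme <- do.call(season_scheme, scheme)
  months <- as.integer(format(track$timestamp, "%m", tz = "UTC"))
  lookup <- character(12)
  for (nm in names(scheme)) lookup[scheme[[nm]]] <- nm
  track$season <- factor(lookup[months], levels = names(scheme))
  track
}

#' Label equal multi-month tracking periods
#'
#' Alternative to the named-season split: consecutive periods of
#' `months_per_period` months each, counted from the animal's first fix
#' (per animal), labelled "P1", "P2", ...
#'
#' @param track A track tibble.
#' @param months_per_period Number of months per period (default 4).
#' @return The track with an added `period` column.
#' @export
assign_periods <- function(track, months_per_period = 4) {
  month_index <- function(ts) {
    as.integer(format(ts, "%Y", tz = "UTC")) * 12L +
      as.integer(format(ts, "%m", tz = "UTC"))
  }
  track |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::mutate(
      period = paste0(
        "P",
        (month_index(.data$timestamp) - min(month_index(.data$timestamp))) %/%
          months_per_period + 1L
      )
    ) |>
    dplyr::ungroup()
}

#' Descriptive movement statistics per animal
#'
#' Steps are Euclidean distances between consecutive fixes of one animal.
#' A step shorter than `stopover_threshold` is counted as stationary;
#' the default of 15 m (about 2.7x a 5.5 m GPS error SD) separates GPS
#' jitter from true movement.
#'
#' @param track A track tibble (one or more animals).
#' @param stopover_threshold Stationary-step cutoff in metres.
#' @return A tibble with one row per animal: `n_fixes`, `mean_step_m`,
#'   `max_step_m`, `total_path_m`, `max_displacement_m` (from the first
#'   fix), `stopover_fraction`, `tracking_days`.
#' @export
movement_summary <- function(track, stopover_threshold = 15) {
  one <- function(d) {
    if (nrow(d) < 2) {
      stop("movement_summary needs at least 2 fixes per animal",
           call. = FALSE)
    }
    dx <- diff(d$x)
    dy <- diff(d$y)
    step <- sqrt(dx^2 + dy^2)
    disp <- sqrt((d$x - d$x[1])^2 + (d$y - d$y[1])^2)
    tibble::tibble(
      n_fixes = nrow(d),
      mean_step_m = mean(step),
      max_step_m = max(step),
      total_path_m = sum(step),
      max_displacement_m = max(disp),
      stopover_fraction = mean(step < stopover_threshold),
      tracking_days = as.numeric(difftime(d$timestamp[nrow(d)],
                                          d$timestamp[1], units = "days"))
    )
  }
  track |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::group_modify(~ one(.x)) |>
    dplyr::ungroup()
}

# Split a (single-animal) track into per-animal list, preserving attributes.
split_by_animal <- function(track) {
  ids <- unique(track$animal_id)
  stats::setNames(lapply(ids, function(id) {
    track[track$animal_id == id, , drop = FALSE]
  }), ids)
}

# Hours between consecutive fixes.
lag_hours <- function(track) {
  as.numeric(difftime(track$timestamp[-1],
                      track$timestamp[-nrow(track)], units = "hours"))
}
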