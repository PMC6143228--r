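#' Percent minimum convex polygon
#'
#' Retains the `ceiling(n * percent / 100)` relocations closest to the
#' arithmetic mean centre of the track (ties broken by retaining the
#' earlier fix first) and returns their convex hull. The ceiling rule never
#' discards more than `(100 - percent)%` of fixes.
#'
#' @param track A single-animal track tibble (or any data frame with `x`,
#'   `y` and optionally `timestamp` columns).
#' @param percent Percentage of fixes retained, in (0, 100].
#' @return A list of class `mcp_region` with `ring` (closed vertex matrix,
#'   counter-clockwise), `area_ha`, `perimeter_m`, `percent`, `n_used`.
#' @export
percent_mcp <- function(track, percent = 95) {
  if (percent <= 0 || percent > 100) {
    stop("`percent` must be in (0, 100]", call. = FALSE)
  }
  if (length(unique(track$animal_id %||% "one")) > 1) {
    stop("percent_mcp expects a single animal; split the track first",
         call. = FALSE)
  }
  n <- nrow(track)
  cx <- mean(track$x)
  cy <- mean(track$y)
  d <- sqrt((track$x - cx)^2 + (track$y - cy)^2)
  ord <- if (!is.null(track$timestamp)) order(d, track$timestamp) else order(d)
  keep <- ord[seq_len(ceiling(n * percent / 100))]
  px <- track$x[keep]
  py <- track$y[keep]

  pts <- unique(cbind(px, py))
  if (nrow(pts) < 3 || all_collinear(pts)) {
    stop("fewer than 3 non-collinear relocations retained: ",
         "cannot build a polygon", call. = FALSE)
  }
  hull <- grDevices::chull(pts[, 1], pts[, 2])
  ring <- pts[rev(hull), , drop = FALSE]        # chull is clockwise; reverse
  ring <- rbind(ring, ring[1, ])                # close the ring
  colnames(ring) <- c("x", "y")
  metrics <- ring_metrics(ring)
  structure(
    list(ring = ring, area_ha = metrics$area_ha,
         perimeter_m = metrics$perimeter_m,
         percent = percent, n_used = length(keep)),
    class = "mcp_region"
  )
}

all_collinear <- function(pts) {
  if (nrow(pts) < 3) return(TRUE)
  v1 <- pts[2, ] - pts[1, ]
  cross <- (pts[, 1] - pts[1, 1]) * v1[2] - (pts[, 2] - pts[1, 2]) * v1[1]
  scale <- max(abs(pts)) + 1
  all(abs(cross) < 1e-9 * scale^2)
}

# Shoelace area (ha) and edge-sum perimeter (m) of a closed ring.
ring_metrics <- function(ring) {
  if (!isTRUE(all.equal(ring[1, ], ring[nrow(ring), ]))) {
    stop("polygon ring is not closed", call. = FALSE)
  }
  x <- ring[, 1]
  y <- ring[, 2]
  n <- nrow(ring)
  area_m2 <- abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
  per <- sum(sqrt(diff(x)^2 + diff(y)^2))
  list(area_ha = area_m2 / 1e4, perimeter_m = per)
}

#' Area and perimeter of a polygon region
#'
#' Area by the shoelace formula (converted to hectares, 1 ha = 10,000 m^2),
#' perimeter as the Euclidean edge sum. Vertex orientation does not affect
#' the (absolute) area.
#'
#' @param region An `mcp_region` or a closed two-column vertex matrix.
#' @return A tibble with `area_ha` and `perimeter_m`.
#' @export
polygon_metrics <- function(region) {
  ring <- if (inherits(region, "mcp_region")) region$ring else as.matrix(region)
  m <- ring_metrics(ring)
  tibble::tibble(area_ha = m$area_ha, perimeter_m = m$perimeter_m)
}

#' @export
print.mcp_region <- function(x, ...) {
  cat(sprintf("<mcp_region> %g%% MCP: %d fixes, %.3f ha, %.1f m perimeter\n",
              x$percent, x$n_used, x$area_ha, x$perimeter_m))
  invisible(x)
}

# Boundary-inclusive point-in-polygon (ray casting with on-edge check).
point_in_ring <- function(ring, x, y) {
  rx <- ring[, 1]; ry <- ring[, 2]
  n <- nrow(ring) - 1
  vapply(seq_along(x), function(k) {
    px <- x[k]; py <- y[k]
    inside <- FALSE
    for (i in seq_len(n)) {
      x1 <- rx[i]; y1 <- ry[i]; x2 <- rx[i + 1]; y2 <- ry[i + 1]
      # on-edge check
      cross <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
      scale <- max(abs(c(x1, y1, x2, y2, px, py))) + 1
      if (abs(cross) < 1e-9 * scale^2 &&
          px >= min(x1, x2) - 1e-9 && px <= max(x1, x2) + 1e-9 &&
          py >= min(y1, y2) - 1e-9 && py <= max(y1, y2) + 1e-9) {
        return(TRUE)
      }
      if ((y1 > py) != (y2 > py)) {
        xint <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
        if (px < xint) inside <- !inside
      }
    }
    inside
  }, logical(1))
}
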