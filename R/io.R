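#' Write a raster to an ESRI ASCII grid (.asc)
#'
#' Plain-text single-band raster interchange format readable by standard
#' GIS tools; used here for UD cell masses (float) and habitat codes
#' (integer).
#'
#' @param x A [ud_raster()] or `habitat_raster`.
#' @param path Output file path.
#' @export
write_asc <- function(x, path) {
  grid <- x$grid
  m <- if (inherits(x, "ud_raster")) x$mass else x$codes
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", grid$n_cols),
    paste("nrows", grid$n_rows),
    paste("xllcorner", format(grid$origin_x, digits = 15)),
    paste("yllcorner", format(grid$origin_y, digits = 15)),
    paste("cellsize", format(grid$cell_size, digits = 15)),
    "NODATA_value -9999"
  ), con)
  # .asc rows run top-to-bottom; our row 1 is the bottom row
  for (r in rev(seq_len(grid$n_rows))) {
    writeLines(paste(format(m[r, ], digits = 10, trim = TRUE),
                     collapse = " "), con)
  }
  if (inherits(x, "habitat_raster")) {
    legend_path <- sub("\\.asc$", "_legend.csv", path)
    utils::write.csv(x$legend, legend_path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a UD raster written by [write_asc()]
#'
#' @param path .asc file path.
#' @return A [ud_raster()].
#' @export
read_ud_asc <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1:6], "\\s+")
  val <- function(i) as.numeric(hdr[[i]][2])
  grid <- grid_spec(val(3), val(4), val(5), val(1), val(2))
  rows <- lapply(lines[-(1:6)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  })
  m <- do.call(rbind, rev(rows))
  ud_raster(grid, m)
}

#' Read a habitat raster written by [write_asc()]
#'
#' @param path .asc file path (a `*_legend.csv` sidecar must sit next to it).
#' @return A `habitat_raster`.
#' @export
read_habitat_asc <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1:6], "\\s+")
  val <- function(i) as.numeric(hdr[[i]][2])
  grid <- grid_spec(val(3), val(4), val(5), val(1), val(2))
  rows <- lapply(lines[-(1:6)], function(l) {
    as.integer(strsplit(trimws(l), "\\s+")[[1]])
  })
  codes <- do.call(rbind, rev(rows))
  legend <- tibble::as_tibble(
    utils::read.csv(sub("\\.asc$", "_legend.csv", path),
                    stringsAsFactors = FALSE)
  )
  structure(list(grid = grid, codes = codes, legend = legend),
            class = "habitat_raster")
}

# Directed boundary segments of a cell region (member on the left),
# chained into closed rings in grid coordinates.
region_rings <- function(region, grid = region$grid) {
  cs <- grid$cell_size
  mask <- region_mask(region, grid)
  member <- function(r, c) {
    r >= 1 && r <= nrow(mask) && c >= 1 && c <= ncol(mask) && mask[r, c]
  }
  segs <- list()
  for (k in seq_len(nrow(region$cells))) {
    r <- region$cells$row[k]
    cc <- region$cells$col[k]
    x0 <- grid$origin_x + (cc - 1) * cs; x1 <- x0 + cs
    y0 <- grid$origin_y + (r - 1) * cs; y1 <- y0 + cs
    if (!member(r - 1, cc)) segs[[length(segs) + 1]] <- c(x0, y0, x1, y0)
    if (!member(r, cc + 1)) segs[[length(segs) + 1]] <- c(x1, y0, x1, y1)
    if (!member(r + 1, cc)) segs[[length(segs) + 1]] <- c(x1, y1, x0, y1)
    if (!member(r, cc - 1)) segs[[length(segs) + 1]] <- c(x0, y1, x0, y0)
  }
  segs <- do.call(rbind, segs)
  key <- function(x, y) paste(round(x / cs * 2), round(y / cs * 2))
  start_key <- key(segs[, 1], segs[, 2])
  lookup <- split(seq_len(nrow(segs)), start_key)
  used <- rep(FALSE, nrow(segs))
  rings <- list()
  for (s0 in seq_len(nrow(segs))) {
    if (used[s0]) next
    ring <- list(segs[s0, 1:2])
    cur <- s0
    repeat {
      used[cur] <- TRUE
      nxt_pt <- segs[cur, 3:4]
      ring[[length(ring) + 1]] <- nxt_pt
      cand <- lookup[[key(nxt_pt[1], nxt_pt[2])]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0) break
      cur <- cand[1]
    }
    rings[[length(rings) + 1]] <- do.call(rbind, ring)
  }
  rings
}

ring_signed_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]; n <- nrow(ring)
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

#' Export regions or MCPs as GeoJSON
#'
#' Isopleth regions are written as MultiPolygons of their traced cell
#' boundaries (counter-clockwise exteriors, clockwise holes grouped into
#' their containing exterior); MCPs as single polygons. Coordinates stay
#' in the projected metric CRS of the input.
#'
#' @param regions A named list of `isopleth_region` / `mcp_region`
#'   objects; names become feature ids.
#' @param path Output file path.
#' @export
write_regions_geojson <- function(regions, path) {
  feature <- function(obj, id) {
    if (inherits(obj, "mcp_region")) {
      geom <- list(type = "Polygon",
                   coordinates = list(unname(apply(obj$ring, 1, c,
                                                   simplify = FALSE))))
      props <- list(id = id, kind = "mcp", percent = obj$percent,
                    area_ha = obj$area_ha, perimeter_m = obj$perimeter_m)
    } else {
      rings <- region_rings(obj)
      areas <- vapply(rings, ring_signed_area, numeric(1))
      ext <- which(areas > 0)
      holes <- which(areas < 0)
      polys <- lapply(ext, function(e) list(rings[[e]]))
      if (length(holes) > 0 && length(ext) > 0) {
        for (h in holes) {
          pt <- rings[[h]][1, ] + c(1e-9, 1e-9)
          containing <- ext[vapply(ext, function(e) {
            point_in_ring(rings[[e]], pt[1], pt[2])
          }, logical(1))]
          if (length(containing) > 0) {
            tgt <- match(containing[1], ext)
            polys[[tgt]] <- c(polys[[tgt]], list(rings[[h]]))
          }
        }
      }
      coords <- lapply(polys, function(p) {
        lapply(p, function(rg) unname(apply(rg, 1, c, simplify = FALSE)))
      })
      geom <- list(type = "MultiPolygon", coordinates = coords)
      props <- list(id = id, kind = "isopleth", level = obj$level,
                    area_ha = obj$area_ha, perimeter_m = obj$perimeter_m,
                    complexity = obj$complexity)
    }
    list(type = "Feature", properties = props, geometry = geom)
  }
  ids <- names(regions) %||% as.character(seq_along(regions))
  fc <- list(
    type = "FeatureCollection",
    features = unname(purrr::imap(regions, function(obj, id) {
      feature(obj, id)
    }))
  )
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a variance profile as an analysis-ready CSV
#'
#' One row per fix: timestamp, per-location motion variance, season and
#' (when a habitat raster is given) habitat — the table downstream mixed
#' models consume.
#'
#' @param profile A [dbbmm_variance_profile()].
#' @param track The aligned track.
#' @param path Output path.
#' @param habitat Optional `habitat_raster`.
#' @param scheme A [season_scheme()].
#' @export
write_profile_csv <- function(profile, track, path, habitat = NULL,
                              scheme = season_scheme()) {
  out <- tibble::tibble(
    animal_id = track$animal_id,
    timestamp = format(track$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    x = track$x, y = track$y,
    sigma2m = profile$sigma2m,
    season = as.character(assign_seasons(track, scheme)$season)
  )
  if (!is.null(habitat)) {
    cells <- point_to_cell(habitat$grid, track$x, track$y)
    code <- ifelse(is.na(cells$row), NA_integer_,
                   habitat$codes[cbind(cells$row, cells$col)])
    out$habitat <- ifelse(
      is.na(code), "unknown",
      habitat$legend$habitat[match(code, habitat$legend$code)]
    )
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
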