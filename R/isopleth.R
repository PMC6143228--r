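#' Isopleth region of a utilization distribution
#'
#' The q% isopleth is the smallest set of cells holding at least a
#' fraction `level` of the UD mass: cells are sorted by mass (descending;
#' ties broken by row then column) and included until the cumulative mass
#' first reaches `level`. Zero-mass cells are never included, so the
#' region is minimal: dropping its last-included cell leaves less than
#' `level`.
#'
#' @param ud A [ud_raster()].
#' @param level Fraction in (0, 1), e.g. 0.50, 0.95, 0.99.
#' @return A list of class `isopleth_region` with `level`, `grid`,
#'   `cells` (tibble of `row`, `col`, `mass`), `mass` (total included) and
#'   the [region_metrics()] fields.
#' @export
isopleth_region <- function(ud, level) {
  stopifnot(inherits(ud, "ud_raster"))
  if (level <= 0 || level >= 1) {
    stop("`level` must be strictly between 0 and 1", call. = FALSE)
  }
  m <- ud$mass
  pos <- which(m > 0, arr.ind = TRUE)
  if (nrow(pos) == 0) stop("UD has no positive cells", call. = FALSE)
  mass <- m[pos]
  ord <- order(-mass, pos[, 1], pos[, 2])
  cum <- cumsum(mass[ord])
  k <- which(cum >= level - 1e-12)[1]
  if (is.na(k)) k <- length(ord)  # all positive cells (mass < level impossible after normalization)
  sel <- ord[seq_len(k)]
  cells <- tibble::tibble(row = as.integer(pos[sel, 1]),
                          col = as.integer(pos[sel, 2]),
                          mass = mass[sel])
  region <- structure(
    list(level = level, grid = ud$grid, cells = cells,
         mass = sum(cells$mass)),
    class = "isopleth_region"
  )
  met <- region_metrics(region, ud$grid)
  region$area_ha <- met$area_ha
  region$perimeter_m <- met$perimeter_m
  region$complexity <- met$complexity
  region
}

#' @export
print.isopleth_region <- function(x, ...) {
  cat(sprintf(
    "<isopleth_region> %.0f%%: %d cells, %.3f ha, %.0f m, complexity %.4f\n",
    100 * x$level, nrow(x$cells), x$area_ha, x$perimeter_m, x$complexity
  ))
  invisible(x)
}

# Logical membership matrix of a region on its grid.
region_mask <- function(region, grid = region$grid) {
  mask <- matrix(FALSE, grid$n_rows, grid$n_cols)
  mask[cbind(region$cells$row, region$cells$col)] <- TRUE
  mask
}

#' Area, perimeter and shape complexity of a cell region
#'
#' Area is `|cells| * cell_size^2 / 10,000` hectares. Perimeter is the
#' rasterized boundary length: `cell_size` times the number of cell edges
#' adjacent to a non-member cell (4-neighborhood; the raster boundary
#' counts). Complexity is perimeter (m) divided by area (ha) — high values
#' mean a boundary-heavy, tightly fitting region.
#'
#' @param region An `isopleth_region` (or any list with a `cells` tibble).
#' @param grid The region's [grid_spec()].
#' @return A tibble with `area_ha`, `perimeter_m`, `complexity`.
#' @export
region_metrics <- function(region, grid = region$grid) {
  cells <- region$cells
  if (is.null(cells) || nrow(cells) == 0) {
    stop("region is empty", call. = FALSE)
  }
  mask <- region_mask(region, grid)
  padded <- matrix(FALSE, nrow(mask) + 2, ncol(mask) + 2)
  padded[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  core <- padded[2:(nrow(mask) + 1), 2:(ncol(mask) + 1), drop = FALSE]
  up    <- padded[1:nrow(mask), 2:(ncol(mask) + 1), drop = FALSE]
  down  <- padded[3:(nrow(mask) + 2), 2:(ncol(mask) + 1), drop = FALSE]
  left  <- padded[2:(nrow(mask) + 1), 1:ncol(mask), drop = FALSE]
  right <- padded[2:(nrow(mask) + 1), 3:(ncol(mask) + 2), drop = FALSE]
  n_edges <- sum(core & !up) + sum(core & !down) +
    sum(core & !left) + sum(core & !right)
  area_ha <- nrow(cells) * grid$cell_size^2 / 1e4
  perimeter_m <- n_edges * grid$cell_size
  tibble::tibble(area_ha = area_ha, perimeter_m = perimeter_m,
                 complexity = perimeter_m / area_ha)
}

#' Overlap between two isopleth regions on a shared grid
#'
#' @param a,b `isopleth_region`s built on the same grid.
#' @return A tibble with `jaccard` (|intersection| / |union|),
#'   `fraction_of_a_in_b` and `fraction_of_b_in_a`.
#' @export
region_overlap <- function(a, b) {
  if (!same_grid(a$grid, b$grid)) {
    stop("regions are on different grids", call. = FALSE)
  }
  ka <- paste(a$cells$row, a$cells$col)
  kb <- paste(b$cells$row, b$cells$col)
  inter <- length(intersect(ka, kb))
  uni <- length(union(ka, kb))
  tibble::tibble(
    jaccard = if (uni == 0) 0 else inter / uni,
    fraction_of_a_in_b = if (length(ka) == 0) 0 else inter / length(ka),
    fraction_of_b_in_a = if (length(kb) == 0) 0 else inter / length(kb)
  )
}
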