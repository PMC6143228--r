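#' Reference grid specification
#'
#' A `grid_spec` describes the axis-aligned raster on which utilization
#' distributions, habitat maps and isopleths live: a lower-left origin in
#' projected metre coordinates, a square cell size and the number of columns
#' and rows. Row 1 is the bottom row; cell `(row, col)` has its centre at
#' `origin + (col - 0.5, row - 0.5) * cell_size`.
#'
#' @param origin_x,origin_y Coordinates (m) of the lower-left corner.
#' @param cell_size Cell edge length in metres; must be positive.
#' @param n_cols,n_rows Grid dimensions; at least 1.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(origin_x, origin_y, cell_size, n_cols, n_rows) {
  if (!is.finite(cell_size) || cell_size <= 0) {
    stop("`cell_size` must be a positive number", call. = FALSE)
  }
  if (n_cols < 1 || n_rows < 1) {
    stop("grid must have at least one row and one column", call. = FALSE)
  }
  structure(
    list(
      origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
      cell_size = as.numeric(cell_size),
      n_cols = as.integer(n_cols), n_rows = as.integer(n_rows)
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d cols x %d rows, cell %g m, origin (%g, %g)\n",
    x$n_cols, x$n_rows, x$cell_size, x$origin_x, x$origin_y
  ))
  invisible(x)
}

#' Build a shared reference grid covering one or more tracks
#'
#' All estimators in a comparison should be evaluated on the same grid and
#' extent, otherwise AUC and area metrics are not comparable across methods.
#' The grid covers the joint bounding box of all relocations, expanded by
#' `buffer` on every side, with the origin snapped down to a multiple of
#' `cell_size` so that grids built from nested data share cell boundaries.
#'
#' @param track A track data frame (may contain several animals) or a list
#'   of track data frames.
#' @param cell_size Cell edge length in metres.
#' @param buffer Extra margin (m) added on every side of the bounding box.
#' @return A [grid_spec()].
#' @export
make_reference_grid <- function(track, cell_size, buffer = 0) {
  if (!is.finite(cell_size) || cell_size <= 0) {
    stop("`cell_size` must be a positive number", call. = FALSE)
  }
  if (is.data.frame(track)) track <- list(track)
  xs <- unlist(lapply(track, function(t) t$x))
  ys <- unlist(lapply(track, function(t) t$y))
  if (length(xs) < 1) stop("need at least one relocation", call. = FALSE)
  x0 <- floor((min(xs) - buffer) / cell_size) * cell_size
  y0 <- floor((min(ys) - buffer) / cell_size) * cell_size
  n_cols <- ceiling((max(xs) + buffer - x0) / cell_size)
  n_rows <- ceiling((max(ys) + buffer - y0) / cell_size)
  grid_spec(x0, y0, cell_size, max(n_cols, 1L), max(n_rows, 1L))
}

# Cell-centre coordinate vectors (length n_cols / n_rows).
grid_centers_x <- function(grid) {
  grid$origin_x + (seq_len(grid$n_cols) - 0.5) * grid$cell_size
}

grid_centers_y <- function(grid) {
  grid$origin_y + (seq_len(grid$n_rows) - 0.5) * grid$cell_size
}

# Map points to (row, col); points on the upper/right edge are clamped into
# the last cell so a grid built to cover the data always contains it.
point_to_cell <- function(grid, x, y) {
  col <- floor((x - grid$origin_x) / grid$cell_size) + 1
  row <- floor((y - grid$origin_y) / grid$cell_size) + 1
  col[x == grid$origin_x + grid$n_cols * grid$cell_size] <- grid$n_cols
  row[y == grid$origin_y + grid$n_rows * grid$cell_size] <- grid$n_rows
  inside <- col >= 1 & col <= grid$n_cols & row >= 1 & row <= grid$n_rows
  tibble::tibble(
    row = ifelse(inside, as.integer(row), NA_integer_),
    col = ifelse(inside, as.integer(col), NA_integer_)
  )
}

grid_covers <- function(grid, x, y) {
  cells <- point_to_cell(grid, x, y)
  !anyNA(cells$row)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-9))
}

#' Construct a utilization-distribution raster
#'
#' @param grid A [grid_spec()].
#' @param mass Numeric matrix (`n_rows` x `n_cols`) of nonnegative cell
#'   masses; normalized to sum to one.
#' @return An object of class `ud_raster`.
#' @export
ud_raster <- function(grid, mass) {
  stopifnot(inherits(grid, "grid_spec"))
  mass <- as.matrix(mass)
  if (nrow(mass) != grid$n_rows || ncol(mass) != grid$n_cols) {
    stop("mass matrix dimensions do not match the grid", call. = FALSE)
  }
  if (any(mass < 0)) stop("cell masses must be nonnegative", call. = FALSE)
  total <- sum(mass)
  if (!is.finite(total) || total <= 0) {
    stop("total UD mass must be positive and finite", call. = FALSE)
  }
  structure(list(grid = grid, mass = mass / total), class = "ud_raster")
}

#' @export
print.ud_raster <- function(x, ...) {
  cat(sprintf(
    "<ud_raster> %d x %d cells (%g m), mass %.6f, %d nonzero cells\n",
    x$grid$n_cols, x$grid$n_rows, x$grid$cell_size,
    sum(x$mass), sum(x$mass > 0)
  ))
  invisible(x)
}
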