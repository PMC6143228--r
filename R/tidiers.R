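#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.ud_raster <- function(x, drop_zero = TRUE, ...) {
  grid <- x$grid
  out <- tidyr::expand_grid(row = seq_len(grid$n_rows),
                            col = seq_len(grid$n_cols))
  out$x <- grid$origin_x + (out$col - 0.5) * grid$cell_size
  out$y <- grid$origin_y + (out$row - 0.5) * grid$cell_size
  out$mass <- x$mass[cbind(out$row, out$col)]
  if (drop_zero) out <- out[out$mass > 0, , drop = FALSE]
  out
}

#' @export
glance.ud_raster <- function(x, ...) {
  tibble::tibble(
    n_cells = length(x$mass), nonzero_cells = sum(x$mass > 0),
    cell_size = x$grid$cell_size, total_mass = sum(x$mass),
    max_mass = max(x$mass)
  )
}

#' @export
tidy.habitat_raster <- function(x, ...) {
  grid <- x$grid
  out <- tidyr::expand_grid(row = seq_len(grid$n_rows),
                            col = seq_len(grid$n_cols))
  out$x <- grid$origin_x + (out$col - 0.5) * grid$cell_size
  out$y <- grid$origin_y + (out$row - 0.5) * grid$cell_size
  out$code <- x$codes[cbind(out$row, out$col)]
  out$habitat <- x$legend$habitat[match(out$code, x$legend$code)]
  out
}

#' @export
glance.habitat_raster <- function(x, ...) {
  counts <- table(factor(x$codes, levels = x$legend$code))
  tibble::tibble(
    habitat = x$legend$habitat,
    target_fraction = x$legend$target_fraction,
    realized_fraction = as.numeric(counts) / length(x$codes)
  )
}

#' @export
tidy.bandwidth_spec <- function(x, ...) {
  x$search_trace %||%
    tibble::tibble(h = x$h_x, score = NA_real_)
}

#' @export
glance.bandwidth_spec <- function(x, ...) {
  tibble::tibble(method = x$method, h_x = x$h_x, h_y = x$h_y,
                 converged = x$converged)
}

#' @export
glance.variance_profile <- function(x, ...) {
  tibble::tibble(
    n_fixes = nrow(x), window = attr(x, "window"),
    margin = attr(x, "margin"),
    mean_sigma2m = mean(x$sigma2m), max_sigma2m = max(x$sigma2m)
  )
}

#' @export
tidy.isopleth_region <- function(x, ...) {
  out <- x$cells
  out$x <- x$grid$origin_x + (out$col - 0.5) * x$grid$cell_size
  out$y <- x$grid$origin_y + (out$row - 0.5) * x$grid$cell_size
  out$level <- x$level
  out
}

#' @export
glance.isopleth_region <- function(x, ...) {
  tibble::tibble(level = x$level, n_cells = nrow(x$cells),
                 mass = x$mass, area_ha = x$area_ha,
                 perimeter_m = x$perimeter_m, complexity = x$complexity)
}

#' @export
tidy.mcp_region <- function(x, ...) {
  tibble::tibble(x = x$ring[, 1], y = x$ring[, 2])
}

#' @export
glance.mcp_region <- function(x, ...) {
  tibble::tibble(percent = x$percent, n_used = x$n_used,
                 area_ha = x$area_ha, perimeter_m = x$perimeter_m)
}

#' @export
tidy.hr_evaluation <- function(x, ...) {
  x$metrics
}

#' @export
glance.hr_evaluation <- function(x, ...) {
  aucs <- x$metrics[x$metrics$metric == "auc", ]
  tidyr::pivot_wider(aucs[, c("animal_id", "method", "value")],
                     names_from = "method", values_from = "value")
}
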