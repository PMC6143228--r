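#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a utilization distribution
#'
#' @param object A [ud_raster()].
#' @param track Optional track to overlay as points.
#' @param trans Transformation for the fill scale (default `"sqrt"`, which
#'   makes low-mass structure visible).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ud_raster <- function(object, track = NULL, trans = "sqrt", ...) {
  d <- tidy(object, drop_zero = TRUE)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$mass)) +
    ggplot2::scale_fill_viridis_c(trans = trans, name = "UD mass") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Easting (m)", y = "Northing (m)") +
    ggplot2::theme_minimal()
  if (!is.null(track)) {
    p <- p + ggplot2::geom_point(
      data = track, ggplot2::aes(x = .data$x, y = .data$y),
      inherit.aes = FALSE, size = 0.3, alpha = 0.4, colour = "white"
    )
  }
  p
}

#' Plot a motion-variance time series
#'
#' @param object A [dbbmm_variance_profile()].
#' @param ... Unused.
#' @return A ggplot of per-location sigma2m over time, one panel per animal.
#' @export
autoplot.variance_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$timestamp,
                                       y = .data$sigma2m)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~animal_id, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = NULL, y = expression(sigma[m]^2 ~ (m^2 / h))) +
    ggplot2::theme_minimal()
}

#' Plot a categorical habitat raster
#'
#' @param object A `habitat_raster`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.habitat_raster <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  fill = .data$habitat)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_brewer(palette = "Set2", name = NULL) +
    ggplot2::labs(x = "Easting (m)", y = "Northing (m)") +
    ggplot2::theme_minimal()
}

#' Plot the estimator comparison
#'
#' @param object An `hr_evaluation` from [compare_estimators()].
#' @param metric One of `"auc"`, `"area_ha"`, `"complexity"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hr_evaluation <- function(object, metric = "auc", ...) {
  d <- object$metrics[object$metrics$metric == metric &
                        object$metrics$season == "all", ]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$method, y = .data$value,
                                       fill = .data$animal_id)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = metric, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
  if (metric %in% c("area_ha", "complexity")) {
    p <- p + ggplot2::facet_wrap(~level, scales = "free_y",
                                 labeller = ggplot2::label_both)
  }
  p
}

#' Overlay isopleth outlines on the relocations
#'
#' @param ud A [ud_raster()].
#' @param track The track the UD came from.
#' @param levels Isopleth levels to outline.
#' @return A ggplot.
#' @export
plot_isopleths <- function(ud, track = NULL, levels = c(0.5, 0.95, 0.99)) {
  cells <- dplyr::bind_rows(lapply(levels, function(lv) {
    tidy(isopleth_region(ud, lv))
  }))
  cells$level <- factor(cells$level, levels = sort(levels, decreasing = TRUE))
  p <- ggplot2::ggplot(cells, ggplot2::aes(x = .data$x, y = .data$y,
                                           fill = .data$level)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_brewer(palette = "YlOrRd", name = "Isopleth") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Easting (m)", y = "Northing (m)") +
    ggplot2::theme_minimal()
  if (!is.null(track)) {
    p <- p + ggplot2::geom_point(
      data = track, ggplot2::aes(x = .data$x, y = .data$y),
      inherit.aes = FALSE, size = 0.2, alpha = 0.3
    )
  }
  p
}
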