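#' Plot a raster grid
#'
#' @param object A [raster_grid()] (including `suitability_map` and
#'   `range_mask`).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.raster_grid <- function(object, ...) {
  cells <- grid_cells(object)
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$x, y = .data$y,
                                      fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "value") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.raster_grid
#' @exportS3Method ggplot2::autoplot
autoplot.binary_map <- function(object, ...) {
  cells <- grid_cells(object)
  cells$state <- factor(cells$value, levels = c(0, 1, 2),
                        labels = c("unsuitable", "suitable", "no consensus"))
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$x, y = .data$y,
                                      fill = .data$state)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(
      values = c(unsuitable = "#d8b365", suitable = "#2c7fb8",
                 `no consensus` = "#bdbdbd"),
      na.value = "white", drop = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot ensemble performance of an experiment
#'
#' One panel per statistic, bars per algorithm and ensemble rule, faceted by
#' training set — the at-a-glance comparison of mean, majority-vote and
#' unanimous-decision ensembles.
#'
#' @param object An `sdm_experiment`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.sdm_experiment <- function(object, ...) {
  tab <- report(object)$table |>
    tidyr::pivot_longer(c("accuracy", "sensitivity", "specificity"),
                        names_to = "statistic")
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$algorithm, y = .data$value,
                                    fill = .data$ensemble)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(ggplot2::vars(.data$statistic),
                        ggplot2::vars(.data$training_set)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "ensemble") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
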