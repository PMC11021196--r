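#' Plot a tissue state
#'
#' Cells as points (fixed ring highlighted), adhesive interactions as grey
#' connection lines, and the cavity rest size as a dashed circle.
#'
#' @param object A `tissue_state`.
#' @param params A [potential_params()] used for the neighbour cutoff.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tissue_state <- function(object, params = potential_params(), ...) {
  cells <- as_tibble(object)
  ng <- neighbor_graph(object, params)
  segs <- dplyr::mutate(
    ng$edges,
    x = cells$x[.data$i], y = cells$y[.data$i],
    xend = cells$x[.data$j], yend = cells$y[.data$j]
  )
  theta <- seq(0, 2 * pi, length.out = 181)
  cavity <- tibble(
    x = object$cavity_center[1] + object$cavity_rest * cos(theta),
    y = object$cavity_center[2] + object$cavity_rest * sin(theta)
  )
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      colour = "grey60", linewidth = 0.2
    ) +
    ggplot2::geom_path(data = cavity, colour = "firebrick",
                       linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$fixed), size = 1.5) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "steelblue", `TRUE` = "grey30"),
      labels = c(`FALSE` = "free", `TRUE` = "fixed"), name = NULL
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("t = %.3g, cavity rest = %.3g",
                      object$time, object$cavity_rest),
      x = NULL, y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot trajectory observables over time
#'
#' Packing index, mean neighbour degree and cavity rest size against
#' simulation time.
#'
#' @param object A `trajectory`.
#' @param ... Unused.
#' @return A ggplot object (facetted by observable).
#' @export
autoplot.trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$observables,
    c("packing_index", "mean_degree", "cavity_rest"),
    names_to = "observable", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~observable, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot grouped measurements behind a comparison
#'
#' Box-and-jitter plot of a `group`/`value` table, the standard view of the
#' per-embryo measurement spreads these tests are run on.
#'
#' @param data Data frame with columns `group` and `value`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_groups <- function(data, ...) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, colour = "steelblue") +
    ggplot2::theme_minimal()
}

#' Display a labelled image channel
#'
#' @param object A `labeled_image`.
#' @param channel Channel index to display.
#' @param ... Unused.
#' @return A ggplot object (raster heat map).
#' @export
autoplot.labeled_image <- function(object, channel = 1, ...) {
  ch <- object$channels[, , channel]
  df <- tidyr::expand_grid(row = seq_len(nrow(ch)), col = seq_len(ncol(ch)))
  df$intensity <- as.vector(ch)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_void()
}
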