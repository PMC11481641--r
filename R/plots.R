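#' Plot methods
#'
#' ggplot2 visualisations of the package's result types: per-year index
#' boxplots for `wq_indices`, a raster map for `wq_raster` (continuous or
#' rank-classified), and an empirical-semivariogram plot with an optional
#' fitted model curve.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name gwindex-plots
NULL

#' @param index `"wqi"` or `"cd"` for the index boxplot.
#' @rdname gwindex-plots
#' @export
autoplot.wq_indices <- function(object, index = c("wqi", "cd"), ...) {
  index <- match.arg(index)
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$year),
                               y = .data[[index]])) +
    ggplot2::geom_boxplot(fill = "steelblue", alpha = 0.6) +
    ggplot2::labs(x = "sampling year",
                  y = if (index == "wqi") "water quality index" else
                    "contamination degree") +
    ggplot2::theme_minimal()
}

#' @rdname gwindex-plots
#' @export
autoplot.wq_raster <- function(object, ...) {
  df <- grid_coords(object)
  df$value <- as.numeric(t(object$values))[
    (df$row - 1) * object$ncol + df$col]
  labels <- attr(object, "labels")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y))
  if (is.null(labels)) {
    p <- p + ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
      ggplot2::scale_fill_viridis_c(na.value = "transparent")
  } else {
    df$rank <- factor(df$value, levels = seq_along(labels), labels = labels)
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
      ggplot2::geom_raster(ggplot2::aes(fill = .data$rank)) +
      ggplot2::scale_fill_brewer(palette = "RdYlGn", direction = -1,
                                 na.value = "transparent", drop = FALSE)
  }
  p + ggplot2::coord_equal() + ggplot2::theme_minimal() +
    ggplot2::labs(x = "easting (m)", y = "northing (m)")
}

#' @param model Optional `wq_variogram` overlaid as a curve.
#' @rdname gwindex-plots
#' @export
autoplot.wq_semivariogram <- function(object, model = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$dist, .data$gamma)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_pairs), alpha = 0.7) +
    ggplot2::labs(x = "separation distance (m)", y = "semivariance",
                  size = "pairs") +
    ggplot2::theme_minimal()
  if (!is.null(model)) {
    h <- seq(0, max(object$dist), length.out = 200)
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(dist = h, gamma = variogram_gamma(model, h)),
      colour = "firebrick")
  }
  p
}

#' Per-year stacked rank-count bars
#'
#' @param counts Output of [count_by_rank()].
#' @param index `"wqi"` or `"cd"` (controls the label set).
#' @return A ggplot object.
#' @export
plot_rank_counts <- function(counts, index = c("wqi", "cd")) {
  index <- match.arg(index)
  labels <- if (index == "wqi") wqi_rank_scale()$label else
    cd_rank_scale()$label
  long <- counts |>
    dplyr::select(-"n") |>
    tidyr::pivot_longer(dplyr::starts_with("rank_"), names_to = "rank",
                        names_prefix = "rank_", values_to = "count") |>
    dplyr::mutate(rank = factor(labels[as.integer(.data$rank)],
                                levels = rev(labels)))
  ggplot2::ggplot(long, ggplot2::aes(factor(.data$year), .data$count,
                                     fill = .data$rank)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "RdYlGn",
                               direction = if (index == "wqi") 1 else 1) +
    ggplot2::labs(x = "sampling year", y = "number of wells", fill = NULL) +
    ggplot2::theme_minimal()
}
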