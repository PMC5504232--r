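#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the permutation null distribution
#'
#' Histogram of the null correlations with the observed model-based
#' correlation marked.
#'
#' @param object a `topography_null` from [topography_null_test()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.topography_null <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_r,
                        colour = "firebrick", linewidth = 1) +
    ggplot2::labs(
      x = "Spearman r (model DCA vs distance from primary)",
      y = "count",
      title = sprintf("Random network topography null (p = %.3g, %d iterations)",
                      object$p_value, object$n_iter)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a network divergence matrix
#' @param object a `divergence_matrix`.
#' @param ... unused.
#' @return a ggplot tile map.
#' @export
autoplot.divergence_matrix <- function(object, ...) {
  nets <- attr(object, "networks") %||% seq_len(nrow(object))
  df <- tidyr::expand_grid(row = factor(nets, levels = nets),
                           col = factor(nets, levels = nets))
  df$jsd <- as.vector(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$jsd)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, log(2)), name = "JSD (nats)") +
    ggplot2::labs(x = "network", y = "network") +
    ggplot2::theme_minimal()
}

#' Plot network distance distributions
#'
#' Density of DCA values per network, ordered by increasing mean.
#'
#' @param dists tibble from [sample_network_distributions()].
#' @return a ggplot.
#' @export
plot_network_distributions <- function(dists) {
  df <- tidyr::unnest(
    dplyr::mutate(dists,
                  network = factor(.data$network, levels = dists$network)),
    "samples")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$samples,
                                   colour = .data$network)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "distance-to-connected-areas", y = "density") +
    ggplot2::theme_minimal()
}

#' Plot the anchoring gradient
#'
#' DCA against distance from the primary seed region, vertex-wise, with a
#' least-squares line -- the scatter behind the headline Spearman
#' correlation.
#'
#' @param dca,distance_from_primary aligned [vertex_map()]s.
#' @param alpha point transparency.
#' @return a ggplot.
#' @export
plot_gradient <- function(dca, distance_from_primary, alpha = 0.2) {
  df <- tibble::tibble(
    distance_from_primary = map_values(as_vertex_map(distance_from_primary)),
    dca = map_values(as_vertex_map(dca))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance_from_primary,
                                   y = .data$dca)) +
    ggplot2::geom_point(alpha = alpha, size = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x,
                         colour = "firebrick", se = FALSE) +
    ggplot2::labs(x = "distance from primary seeds",
                  y = "distance-to-connected-areas") +
    ggplot2::theme_minimal()
}

#' Plot a threshold sweep
#' @param sweep tibble from [threshold_sweep()].
#' @return a ggplot of vertexwise median DCA against threshold.
#' @export
plot_threshold_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$percent, y = .data$median)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "connectivity threshold (% highest per node)",
                  y = "median distance-to-connected-areas") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
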