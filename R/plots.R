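#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmaps of the state centroids
#'
#' One Fisher-z connectivity heatmap per state, the standard rendering of
#' cluster centroids in dFNC analyses.
#'
#' @param object A `state_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.state_model <- function(object, ...) {
  td <- tidy(object)
  full <- dplyr::bind_rows(td, dplyr::rename(td, i = "j", j = "i"))
  ggplot2::ggplot(full, ggplot2::aes(x = .data$j, y = .data$i,
                                     fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", name = "Fisher z") +
    ggplot2::facet_wrap(~state, labeller = ggplot2::label_both) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "component", y = "component",
                  title = "Connectivity state centroids") +
    ggplot2::theme_minimal()
}

#' Box plots of temporal dynamics metrics by group
#'
#' @param dynamics Tibble from [cohort_dynamics()].
#' @param metric `"dwell_time"`, `"fraction_time"` or `"n_transitions"`.
#' @return A ggplot object.
#' @export
plot_dynamics <- function(dynamics, metric = c("dwell_time", "fraction_time",
                                               "n_transitions")) {
  metric <- match.arg(metric)
  if (metric == "n_transitions") {
    d <- dplyr::distinct(dynamics, .data$subject_id, .data$group,
                         .data$n_transitions)
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$group,
                                         y = .data$n_transitions,
                                         fill = .data$group)) +
      ggplot2::geom_boxplot()
  } else {
    p <- ggplot2::ggplot(
      dynamics[dynamics$entered | metric == "fraction_time", ],
      ggplot2::aes(x = factor(.data$state), y = .data[[metric]],
                   fill = .data$group)) +
      ggplot2::geom_boxplot() +
      ggplot2::labs(x = "state")
  }
  p + ggplot2::labs(y = metric) + ggplot2::theme_minimal()
}

#' Edgewise group-difference map for one state
#'
#' Renders the t statistics of a [compare_state_fnc()] comparison as a
#' component-by-component half matrix, marking FDR-significant edges.
#'
#' @param stats Tibble from [compare_state_fnc()].
#' @param state State to plot (default: first present).
#' @return A ggplot object.
#' @export
plot_edge_differences <- function(stats, state = min(stats$state)) {
  d <- stats[stats$state == state, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$j, y = .data$i,
                                  fill = .data$t)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = d[d$significant, ], size = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", name = "t") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("%s - %s, state %d (dots: FDR-significant)",
                      d$group_a[1], d$group_b[1], state),
      x = "component", y = "component") +
    ggplot2::theme_minimal()
}
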