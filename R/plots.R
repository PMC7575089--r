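#' @exportS3Method ggplot2::autoplot
autoplot.link_plan <- function(object, ...) {
  traj <- tibble(links_added = c(0, object$links$rank),
                 clustering = c(object$initial_C, object$links$clustering_after))
  ggplot2::ggplot(traj, ggplot2::aes(x = .data$links_added, y = .data$clustering)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "links added", y = "clustering coefficient",
                  title = paste0("strategy: ", object$strategy)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.robustness_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$loss, y = .data$occupancy)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$occupancy - .data$se,
                                      ymax = .data$occupancy + .data$se),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "fraction of habitat patches lost",
                  y = "fraction of colonised patches",
                  subtitle = sprintf("AUC = %.3f", attr(object, "auc"))) +
    ggplot2::theme_minimal()
}

#' Plot a strategy comparison table
#'
#' Boxplots of the robustness gain (change in AUC) by number of added links
#' and strategy, as produced by [compare_strategies()] over one or more
#' networks.
#'
#' @param results A tibble with columns `m`, `delta_auc`, `strategy`.
#' @return A ggplot object.
#' @export
plot_strategy_comparison <- function(results) {
  ggplot2::ggplot(results,
                  ggplot2::aes(x = factor(.data$m), y = .data$delta_auc,
                               fill = .data$strategy)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "links added", y = expression(Delta * "AUC"),
                  fill = "strategy") +
    ggplot2::theme_minimal()
}
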