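# ggplot2 views of the standard result tables

#' Heatmap of mean AUC by phase combination and region class
#'
#' @param summary a [aggregate_phase_region()] result.
#' @return a ggplot object.
#' @export
plot_phase_region <- function(summary) {
  abort_if(!inherits(summary, "benchmark_summary"),
           "`summary` must be a benchmark_summary")
  ggplot2::ggplot(summary$phase_region,
                  ggplot2::aes(x = .data$region_class, y = .data$phase_combo,
                               fill = .data$mean_auc)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$mean_auc)),
                       size = 3) +
    ggplot2::scale_fill_viridis_c(name = "mean AUC") +
    ggplot2::labs(x = "region class", y = "phase combination",
                  title = "Prediction performance by phase and region")
}

#' Mean AUC trend over peritumoral distance
#'
#' @param summary a [aggregate_phase_region()] result.
#' @return a ggplot object.
#' @export
plot_distance_trend <- function(summary) {
  abort_if(!inherits(summary, "benchmark_summary"),
           "`summary` must be a benchmark_summary")
  ggplot2::ggplot(summary$distance_trend,
                  ggplot2::aes(x = .data$distance, y = .data$mean_auc,
                               colour = .data$region_class)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "peritumoral distance (mm)", y = "mean AUC",
                  colour = "region class",
                  title = "AUC trend over peritumoral distance")
}

#' @export
autoplot.benchmark_summary <- function(object, ...) {
  plot_phase_region(object)
}

#' Pairwise NRI matrix heatmap
#'
#' @param x a [fuse_top_models()] result or the tibble from [nri_matrix()].
#' @return a ggplot object.
#' @export
plot_nri_matrix <- function(x) {
  long <- if (inherits(x, "fusion_result")) x$nri else x
  ggplot2::ggplot(long, ggplot2::aes(x = .data$model_x, y = .data$model_y,
                                     fill = .data$nri)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$nri)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(low = "steelblue", high = "firebrick",
                                  mid = "white", midpoint = 0, name = "NRI") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Net reclassification improvement (row vs column)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @export
autoplot.fusion_result <- function(object, ...) {
  plot_nri_matrix(object)
}

#' Top-feature census bar chart
#'
#' @param census tibble from [top_feature_census()].
#' @param n_show number of features displayed (default 15).
#' @return a ggplot object.
#' @export
plot_feature_census <- function(census, n_show = 15) {
  top <- head(dplyr::arrange(census, dplyr::desc(.data$percentage)), n_show)
  ggplot2::ggplot(top, ggplot2::aes(x = .data$percentage,
                                    y = stats::reorder(.data$feature,
                                                       .data$percentage))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "selection percentage (%)", y = NULL,
                  title = "Most frequently selected features")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
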