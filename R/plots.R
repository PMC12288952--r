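#' Loss-curve plot for a trained model
#'
#' @param object An `m6a_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.m6a_fit <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(colour = "#4477AA") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "epoch", y = "training loss (binary cross-entropy)",
                  title = paste0(object$spec$variant, " training history")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' ROC curve plot
#'
#' @param truth Binary labels.
#' @param prob Predicted probabilities.
#' @param label Curve label used in the subtitle.
#' @return A ggplot object (the AUC is printed in the subtitle).
#' @export
plot_roc <- function(truth, prob, label = NULL) {
  pts <- roc_points(truth, prob)
  auc <- auc_roc(truth, prob)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_path(colour = "#EE6677") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = label %||% "ROC",
                  subtitle = sprintf("AUC = %.3f", auc)) +
    ggplot2::theme_minimal()
}

#' Box plot of per-fold metrics
#'
#' Visualizes the spread of evaluation metrics across folds (for LOCO:
#' across held-out chromosomes), optionally grouped by model variant.
#'
#' @param reports Tibble of per-fold report rows ([evaluate_predictions()]
#'   format), with an optional `variant` column for grouping.
#' @param metrics Metric columns to show.
#' @return A ggplot object.
#' @export
plot_metric_box <- function(reports,
                            metrics = c("accuracy", "sensitivity",
                                        "specificity", "auc")) {
  long <- tidyr::pivot_longer(reports, dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  has_variant <- "variant" %in% names(long)
  p <- ggplot2::ggplot(long, ggplot2::aes(
    x = .data$metric, y = .data$value,
    fill = if (has_variant) .data$variant else NULL))
  p + ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "value", fill = if (has_variant) "variant") +
    ggplot2::theme_minimal()
}
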