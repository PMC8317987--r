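#' Plot an evaluation report
#'
#' Distributions of the per-iteration test metrics (accuracy, AUC,
#' sensitivity, specificity) across the repeated splits.
#'
#' @param object An `evaluation_report`.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @method autoplot evaluation_report
#' @export
autoplot.evaluation_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object$per_iteration, "iteration", "accuracy",
                  "sensitivity", "specificity", "auc"),
    -"iteration", names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey85") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = NULL, y = "test-set value",
                  title = paste0("Repeated-split performance (",
                                 nrow(object$per_iteration),
                                 " iterations, ", object$selector, ")")) +
    ggplot2::theme_minimal()
}

#' Plot feature selection frequencies
#'
#' Bar chart of the most frequently selected features over the protocol
#' iterations.
#'
#' @param report An `evaluation_report`.
#' @param n Number of top features to show (default 60).
#'
#' @return A ggplot object.
#' @export
plot_selection_frequency <- function(report, n = 60) {
  top <- top_selected_features(report, n)
  top$feature <- factor(top$feature, levels = rev(top$feature))
  ggplot2::ggplot(top, ggplot2::aes(x = .data$frequency, y = .data$feature)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "selection frequency", y = NULL,
                  title = paste("Top", nrow(top),
                                "features by selection frequency")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6))
}

#' Plot a selection result
#'
#' For an Enet-subset result, the cross-validated AUC trace over subset
#' sizes with the chosen size marked; for a plain elastic-net result,
#' the ranked absolute coefficients.
#'
#' @param object A `selection_result`.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @method autoplot selection_result
#' @export
autoplot.selection_result <- function(object, ...) {
  if (!is.null(object$subset_trace)) {
    ggplot2::ggplot(object$subset_trace,
                    ggplot2::aes(x = .data$size, y = .data$cv_auc)) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::geom_vline(xintercept = object$best_size, linetype = 2,
                          colour = "firebrick") +
      ggplot2::labs(x = "subset size (top features by |coefficient|)",
                    y = "nested CV AUC",
                    title = "Enet-subset size selection") +
      ggplot2::theme_minimal()
  } else {
    d <- dplyr::mutate(object$coefficients, rank = dplyr::row_number())
    ggplot2::ggplot(d, ggplot2::aes(x = .data$rank,
                                    y = abs(.data$coefficient))) +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::labs(x = "coefficient rank", y = "|coefficient|",
                    title = "Elastic-net coefficient magnitudes") +
      ggplot2::theme_minimal()
  }
}

#' Plot a permutation null distribution
#'
#' @param object A `permutation_null`.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @method autoplot permutation_null
#' @export
autoplot.permutation_null <- function(object, ...) {
  d <- tibble::tibble(value = object$null_values)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey80", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick") +
    ggplot2::labs(x = paste("permuted", object$statistic),
                  y = "count",
                  title = sprintf("Permutation null (p = %.4g, %d permutations)",
                                  object$p_value, object$n_perm)) +
    ggplot2::theme_minimal()
}
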