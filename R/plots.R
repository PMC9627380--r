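#' Plot a ROC curve
#'
#' @param object An `eppm_roc`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eppm_roc <- function(object, ...) {
  pts <- object$points
  pts <- pts[order(1 - pts$specificity, pts$sensitivity), ]
  ggplot2::ggplot(pts, ggplot2::aes(x = 1 - .data$specificity,
                                    y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("AUC %.3f (95%% CI %.3f-%.3f)",
                      object$auc, object$auc_ci[1], object$auc_ci[2])
    ) +
    ggplot2::theme_minimal()
}

#' Plot the per-set ROC curves of an evaluation
#'
#' @param object An `eppm_evaluation`.
#' @param ... Unused.
#' @return A ggplot with one ROC curve per evaluated set.
#' @export
autoplot.eppm_evaluation <- function(object, ...) {
  pts <- purrr::imap_dfr(object$sets, function(res, nm) {
    dplyr::mutate(res$roc$points,
                  set = sprintf("%s (AUC %.3f)", nm, res$roc$auc))
  })
  pts <- pts[order(pts$set, 1 - pts$specificity, pts$sensitivity), ]
  ggplot2::ggplot(pts, ggplot2::aes(x = 1 - .data$specificity,
                                    y = .data$sensitivity,
                                    colour = .data$set)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity", colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' Score distribution by outcome
#'
#' Histogram of EPPM totals split by outcome, with an optional decision
#' threshold marked.
#'
#' @param data A scored cohort (output of [score_cohort()]) with outcome
#'   labels.
#' @param threshold Optional threshold drawn as a vertical line.
#' @return A ggplot.
#' @export
plot_score_distribution <- function(data, threshold = 23.5) {
  stopifnot("total" %in% names(data), "outcome" %in% names(data))
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$total,
                                          fill = .data$outcome)) +
    ggplot2::geom_histogram(binwidth = 1, position = "identity",
                            alpha = 0.55, colour = "grey30") +
    ggplot2::labs(x = "EPPM total score", y = "Patients", fill = "Outcome") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold, linetype = "dashed")
  }
  p
}
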