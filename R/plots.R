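#' Plot raw versus filtered Hits@k of an evaluation report
#'
#' @param object A `prd_eval_report` from [aggregate_metrics()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot prd_eval_report
#' @export
autoplot.prd_eval_report <- function(object, ...) {
  hits <- object[grepl("^hits_at_", object$metric), ]
  hits$k <- factor(as.integer(sub("hits_at_", "", hits$metric)))
  ggplot2::ggplot(hits, ggplot2::aes(x = .data$k, y = .data$value,
                                     fill = .data$setting)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "k", y = "Hits@k (x100)", fill = "setting",
                  title = "Label ranking accuracy") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Plot the ROC and precision-recall curves of a binary evaluation
#'
#' @param object A `prd_binary_eval` from [binary_evaluate()].
#' @param which `"roc"` or `"pr"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot prd_binary_eval
#' @export
autoplot.prd_binary_eval <- function(object, which = c("roc", "pr"), ...) {
  which <- match.arg(which)
  if (which == "roc") {
    ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
      ggplot2::geom_step() +
      ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
      ggplot2::labs(x = "False positive rate", y = "True positive rate",
                    title = sprintf("ROC (AUROC = %.3f)", object$auroc)) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$pr, ggplot2::aes(x = .data$recall,
                                            y = .data$precision)) +
      ggplot2::geom_step(direction = "vh") +
      ggplot2::labs(x = "Recall", y = "Precision",
                    title = sprintf("Precision-recall (AUPR = %.3f)",
                                    object$aupr)) +
      ggplot2::ylim(0, 1) +
      ggplot2::theme_minimal()
  }
}

#' Plot the training objective trace
#'
#' @param model A `prd_model`.
#' @param window Rolling-mean window for the smoothed overlay.
#' @return A ggplot object.
#' @export
plot_training_trace <- function(model, window = 10) {
  tr <- model$trace
  tr$smoothed <- stats::filter(tr$objective, rep(1 / window, window),
                               sides = 1)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$iteration)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$objective),
                       colour = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), colour = "black",
                       na.rm = TRUE) +
    ggplot2::labs(x = "Iteration", y = "Batch objective",
                  title = "Training objective (grey: raw, black: smoothed)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
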