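#' Plot ROC and precision-recall curves of an evaluation
#'
#' @param object a `pepn_eval` result from [evaluate_ranking()].
#' @param curve `"roc"` or `"pr"`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot pepn_eval
#' @export
autoplot.pepn_eval <- function(object, curve = c("roc", "pr"), ...) {
  curve <- match.arg(curve)
  curves <- attr(object, "curves")
  if (curve == "roc") {
    d <- dplyr::bind_rows(tibble::tibble(fpr = 0, tpr = 0), curves$roc)
    ggplot2::ggplot(d, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
      ggplot2::geom_step() +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
      ggplot2::labs(
        x = "False positive rate", y = "True positive rate",
        title = sprintf("ROC (AUROC = %.3f)", object$auroc)
      )
  } else {
    ggplot2::ggplot(curves$pr, ggplot2::aes(x = .data$recall, y = .data$precision)) +
      ggplot2::geom_step(direction = "vh") +
      ggplot2::geom_hline(yintercept = object$baseline_aupr, linetype = "dotted") +
      ggplot2::ylim(0, 1) +
      ggplot2::labs(
        x = "Recall", y = "Precision",
        title = sprintf("Precision-recall (AUPR = %.3f)", object$aupr)
      )
  }
}

#' Plot learned evidence weights of a v3 fit
#'
#' Bar chart of the per-evidence logistic weights, averaged across folds,
#' split by model class (activation / inhibition, or the single unsigned
#' edge model).
#'
#' @param object a `pepn_v3_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot pepn_v3_fit
#' @export
autoplot.pepn_v3_fit <- function(object, ...) {
  w <- tidy(object)
  w <- w[w$term != "w0", ]
  w <- dplyr::summarise(
    dplyr::group_by(w, .data$model, .data$evidence),
    estimate = mean(.data$estimate), .groups = "drop"
  )
  ggplot2::ggplot(w, ggplot2::aes(
    x = factor(.data$evidence, levels = paste0("Pr_", c("PE", "DE", "SPE", "SDE"))),
    y = .data$estimate, fill = .data$model
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = "Evidence type", y = "Mean learned weight", fill = "Model",
      title = "Evidence-type contributions to edge prediction"
    )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
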