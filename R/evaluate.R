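# Benchmarking: confusion metrics at each stringency threshold, ROC/AUC,
# with broom-style tidiers and a ggplot2 ROC plot.

#' Evaluate predictions against known labels
#'
#' @param predictions Tibble from [predict.map_predictor()], or any tibble
#'   with an `id` column and the score column named by `score_col`; a bare
#'   numeric vector of scores also works.
#' @param labels Labels aligned with the scores: either a vector, or a
#'   dataset/label tibble with `id` and `label` columns matched by id.
#' @param thresholds Threshold tibble (`level`, `value`); default
#'   [stringency_thresholds()].
#' @param score_col Name of the score column (default `"s_combined"`).
#' @return An object of class `map_evaluation`: per-threshold confusion
#'   counts and metrics, ROC points and AUC.
#' @export
map_evaluate <- function(predictions, labels, thresholds = stringency_thresholds(),
                         score_col = "s_combined") {
  if (is.data.frame(predictions)) {
    if (!score_col %in% names(predictions)) {
      abort(sprintf("no '%s' column in predictions", score_col))
    }
    scores <- predictions[[score_col]]
    if (is.data.frame(labels)) {
      idx <- match(predictions$id, labels$id)
      if (anyNA(idx)) abort("some prediction ids are missing from the label table")
      labels <- labels$label[idx]
    }
  } else {
    scores <- as.numeric(predictions)
  }
  keep <- !as.character(labels) %in% c("unlabeled", "unknown")
  scores <- scores[keep]
  labels <- labels[keep]
  rows <- map(seq_len(nrow(thresholds)), function(i) {
    cc <- confusion_counts(scores, labels, thresholds$value[i])
    dplyr::bind_cols(tibble(level = thresholds$level[i], threshold = thresholds$value[i]),
                     cc, confusion_metrics(cc))
  })
  ra <- roc_auc(scores, labels)
  structure(list(metrics = bind_rows(rows), roc_points = ra$roc_points,
                 auc = ra$auc, n_pos = sum(as_pm1(labels) > 0),
                 n_neg = sum(as_pm1(labels) < 0)),
            class = "map_evaluation")
}

#' @export
print.map_evaluation <- function(x, ...) {
  cat(sprintf("MAP predictor evaluation: %d positives, %d negatives, AUC = %.3f\n",
              x$n_pos, x$n_neg, x$auc))
  print(x$metrics, ...)
  invisible(x)
}

#' @export
tidy.map_evaluation <- function(x, ...) x$metrics

#' @export
glance.map_evaluation <- function(x, ...) {
  tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' ROC curve plot for an evaluation
#'
#' @param object A `map_evaluation`.
#' @param ... Unused.
#' @return A ggplot object: the ROC curve with the chance diagonal and the
#'   AUC in the subtitle.
#' @export
autoplot.map_evaluation <- function(object, ...) {
  ggplot2::ggplot(object$roc_points, ggplot2::aes(x = fpr, y = tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False-positive rate (1 - specificity)",
                  y = "True-positive rate (sensitivity)",
                  title = "MAP predictor ROC",
                  subtitle = sprintf("AUC = %.3f (%d positives, %d negatives)",
                                     object$auc, object$n_pos, object$n_neg)) +
    ggplot2::theme_minimal()
}
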