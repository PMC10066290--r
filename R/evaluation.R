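## Confusion-matrix evaluation with cobra as the positive class.

#' Build a 2x2 confusion matrix
#'
#' @param true_labels,predicted_labels equal-length character vectors over
#'   `{"cobra", "other"}`; cobra is the positive class.
#' @return a `confusion_matrix`: list with integer counts `tp`, `fn`, `fp`,
#'   `tn`.
#' @export
#' @examples
#' confusion(c("cobra", "cobra", "other"), c("cobra", "other", "cobra"))
confusion <- function(true_labels, predicted_labels) {
  fm_assert(length(true_labels) == length(predicted_labels), "metrics",
            "label vectors differ in length (%d vs %d)",
            length(true_labels), length(predicted_labels))
  ok <- c(true_labels, predicted_labels) %in% bite_labels()
  fm_assert(all(ok), "metrics", "labels must be in {%s}",
            paste(bite_labels(), collapse = ", "))
  pos <- true_labels == "cobra"
  ppos <- predicted_labels == "cobra"
  confusion_matrix(tp = sum(pos & ppos), fn = sum(pos & !ppos),
                   fp = sum(!pos & ppos), tn = sum(!pos & !ppos))
}

#' Construct a confusion matrix from counts
#'
#' @param tp,fn,fp,tn non-negative counts.
#' @return a `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  fm_assert(all(counts >= 0), "metrics", "confusion counts must be >= 0")
  structure(as.list(as.integer(counts)), names = names(counts),
            class = "confusion_matrix")
}

cm_total <- function(cm) cm$tp + cm$fn + cm$fp + cm$tn

#' Sensitivity (true positive rate): `tp / (tp + fn)`
#' @param cm a [confusion_matrix()].
#' @return fraction in [0, 1].
#' @export
sensitivity <- function(cm) {
  fm_assert(cm$tp + cm$fn >= 1, "metrics", "sensitivity undefined: tp + fn = 0")
  cm$tp / (cm$tp + cm$fn)
}

#' Specificity (true negative rate): `tn / (tn + fp)`
#' @param cm a [confusion_matrix()].
#' @return fraction in [0, 1].
#' @export
specificity <- function(cm) {
  fm_assert(cm$tn + cm$fp >= 1, "metrics", "specificity undefined: tn + fp = 0")
  cm$tn / (cm$tn + cm$fp)
}

#' Overall accuracy: `(tp + tn) / total`
#' @param cm a [confusion_matrix()].
#' @return fraction in [0, 1].
#' @export
accuracy <- function(cm) {
  fm_assert(cm_total(cm) >= 1, "metrics", "accuracy undefined on an empty matrix")
  (cm$tp + cm$tn) / cm_total(cm)
}

#' Area under the ROC curve
#'
#' The rank-based estimator: the probability that a randomly chosen positive
#' case outscores a randomly chosen negative one, with tied scores counting
#' one half. Equals brute-force counting over all positive-negative pairs.
#'
#' @param scores numeric scores (higher = more cobra-like).
#' @param true_labels labels over `{"cobra", "other"}`; both classes must be
#'   present.
#' @return value in [0, 1].
#' @export
#' @examples
#' auc(c(0.1, 0.4, 0.35, 0.8), c("other", "other", "cobra", "cobra"))  # 0.75
auc <- function(scores, true_labels) {
  fm_assert(length(scores) == length(true_labels), "metrics",
            "scores and labels differ in length")
  pos <- true_labels == "cobra"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  fm_assert(n_pos >= 1 && n_neg >= 1, "metrics",
            "AUC needs both classes present (got %d positive, %d negative)",
            n_pos, n_neg)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Evaluate a trained model on labelled images
#'
#' @param model a trained `fang_model`.
#' @param dataset list of `labeled_image`.
#' @return list with the confusion counts and `sensitivity`, `specificity`,
#'   `accuracy`, `auc` (fractions; scale to percentages only at reporting).
#' @export
evaluate_model <- function(model, dataset) {
  fm_assert(isTRUE(model$trained), "evaluate", "model is untrained")
  truth <- vapply(dataset, function(d) d$label, character(1))
  pred <- predict(model, dataset)
  cm <- confusion(truth, pred$label)
  out <- list(tp = cm$tp, fn = cm$fn, fp = cm$fp, tn = cm$tn,
              sensitivity = sensitivity(cm), specificity = specificity(cm),
              accuracy = accuracy(cm))
  out$auc <- if (length(unique(truth)) == 2) auc(pred$score, truth) else NA_real_
  out
}
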