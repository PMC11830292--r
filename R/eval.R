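# Confusion matrices, classification metrics and ROC/AUC. The abnormal class
# is the positive class throughout.

#' Confusion matrix of binary heart-sound predictions
#'
#' @param truth,predicted Vectors of `"normal"`/`"abnormal"` labels (or
#'   factors), equal length.
#' @return A `pcg_confusion` with counts `tp`, `tn`, `fp`, `fn`
#'   (positive = abnormal); they sum to the number of evaluated segments.
#' @export
confusion <- function(truth, predicted) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  pcg_assert(length(truth) == length(predicted), "pcgnet_validation_error",
             "truth and predicted must have equal length")
  bad <- setdiff(unique(c(truth, predicted)), c("normal", "abnormal"))
  pcg_assert(length(bad) == 0, "pcgnet_validation_error",
             sprintf("unknown label value(s): %s", paste(bad, collapse = ", ")))
  structure(list(
    tp = sum(truth == "abnormal" & predicted == "abnormal"),
    tn = sum(truth == "normal" & predicted == "normal"),
    fp = sum(truth == "normal" & predicted == "abnormal"),
    fn = sum(truth == "abnormal" & predicted == "normal")),
    class = "pcg_confusion")
}

#' Build a confusion matrix directly from counts
#' @param tp,tn,fp,fn Non-negative cell counts.
#' @return A `pcg_confusion`.
#' @export
confusion_from_counts <- function(tp, tn, fp, fn) {
  pcg_assert(all(c(tp, tn, fp, fn) >= 0), "pcgnet_validation_error",
             "counts must be non-negative")
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn), class = "pcg_confusion")
}

#' @export
print.pcg_confusion <- function(x, ...) {
  cat(sprintf("<pcg_confusion> tp=%d tn=%d fp=%d fn=%d (n=%d)\n",
              x$tp, x$tn, x$fp, x$fn, x$tp + x$tn + x$fp + x$fn))
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy `(tp+tn)/n`, precision `tp/(tp+fp)`, recall (sensitivity)
#' `tp/(tp+fn)`, F1 (harmonic mean of precision and recall) and specificity
#' `tn/(tn+fp)`. A ratio with a zero denominator is reported as `NA` and
#' named in the `undefined` field, never silently set to 0.
#'
#' @param cm A `pcg_confusion` with at least one count.
#' @return A `pcg_metrics` list with fields `accuracy`, `precision`,
#'   `recall`, `f1`, `specificity`, `undefined`.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "pcg_confusion"))
  total <- cm$tp + cm$tn + cm$fp + cm$fn
  pcg_assert(total > 0, "pcgnet_validation_error", "empty confusion matrix")
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- safe_div(cm$tp, cm$tp + cm$fp)
  recall <- safe_div(cm$tp, cm$tp + cm$fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  m <- list(accuracy = (cm$tp + cm$tn) / total,
            precision = precision, recall = recall, f1 = f1,
            specificity = safe_div(cm$tn, cm$tn + cm$fp))
  m$undefined <- names(which(vapply(m[1:5], is.na, logical(1))))
  structure(m, class = "pcg_metrics")
}

#' @export
print.pcg_metrics <- function(x, ...) {
  cat(sprintf("<pcg_metrics> acc=%.4f prec=%.4f rec=%.4f f1=%.4f spec=%.4f\n",
              x$accuracy, x$precision, x$recall, x$f1, x$specificity))
  if (length(x$undefined) > 0)
    cat("  undefined (zero denominator):", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' ROC curve and area under it
#'
#' The curve is built by sweeping every distinct score as a decision
#' threshold (ties grouped into one step); the AUC is the trapezoidal
#' integral of TPR over FPR, which equals the Mann-Whitney pair statistic.
#'
#' @param truth Labels `"normal"`/`"abnormal"` (or 0/1 with 1 = abnormal).
#' @param scores P(abnormal) per segment. Both classes must be present.
#' @return A `pcg_roc` with non-decreasing `fpr` and `tpr` starting at (0,0)
#'   and ending at (1,1), decreasing `thresholds` (first `Inf`), and `auc`.
#' @export
roc_auc <- function(truth, scores) {
  if (is.character(truth) || is.factor(truth))
    truth <- as.integer(as.character(truth) == "abnormal")
  pcg_assert(length(truth) == length(scores), "pcgnet_validation_error",
             "truth and scores must have equal length")
  n_pos <- sum(truth == 1); n_neg <- sum(truth == 0)
  pcg_assert(n_pos > 0 && n_neg > 0, "pcgnet_validation_error",
             "ROC needs at least one positive and one negative label")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- truth[ord]
  # group tied scores into single threshold steps
  last_of_group <- c(s[-length(s)] != s[-1], TRUE)
  cum_tp <- cumsum(y)[last_of_group]
  cum_fp <- cumsum(1 - y)[last_of_group]
  tpr <- c(0, cum_tp / n_pos)
  fpr <- c(0, cum_fp / n_neg)
  thresholds <- c(Inf, s[last_of_group])
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(fpr = fpr, tpr = tpr, thresholds = thresholds, auc = auc),
            class = "pcg_roc")
}

#' @export
print.pcg_roc <- function(x, ...) {
  cat(sprintf("<pcg_roc> %d points, AUC = %.4f\n", length(x$fpr), x$auc))
  invisible(x)
}

#' Evaluate a trained model on a held-out dataset
#'
#' Runs the forward pass, derives hard labels at the 0.5 threshold and
#' assembles confusion cells, the five metrics, and the ROC curve with AUC.
#'
#' @param model A trained `pcg_cnn`.
#' @param test_set A [pcg_dataset] containing both classes.
#' @param path Optional path; when given the report is written as JSON.
#' @return A list with `confusion`, `metrics`, `roc` (and `n`).
#' @export
evaluate_model <- function(model, test_set, path = NULL) {
  probs <- model_forward(model, test_set)
  p_ab <- prob_abnormal(probs)
  truth <- vapply(test_set$segments, `[[`, character(1), "label")
  predicted <- ifelse(p_ab > 0.5, "abnormal", "normal")
  cm <- confusion(truth, predicted)
  metrics <- compute_metrics(cm)
  roc <- roc_auc(truth, p_ab)
  report <- list(n = length(truth), confusion = cm[c("tp", "tn", "fp", "fn")],
                 metrics = metrics[c("accuracy", "precision", "recall",
                                     "f1", "specificity")],
                 auc = roc$auc,
                 roc = list(fpr = roc$fpr, tpr = roc$tpr))
  if (!is.null(path))
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  c(report, list(roc_obj = roc, confusion_obj = cm))
}
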