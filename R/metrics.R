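#' Pixelwise confusion counts
#'
#' @param pred,truth binary matrices (or vectors) of identical shape.
#' @return named integer vector `(TP, FP, FN, TN)`; the four counts sum to
#'   the number of pixels.
#' @export
confusion_counts <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth)) || length(pred) != length(truth))
    stop_input("pred and truth shapes differ")
  if (!all(pred %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    stop_input("masks must be binary (0/1)")
  p <- as.logical(pred); t <- as.logical(truth)
  c(TP = sum(p & t), FP = sum(p & !t), FN = sum(!p & t), TN = sum(!p & !t))
}

metric_from_counts <- function(cc, which) {
  tp <- cc[["TP"]]; fp <- cc[["FP"]]; fn <- cc[["FN"]]; tn <- cc[["TN"]]
  # 0/0 convention: when the reference set defining the denominator is
  # empty the metric is 1 (a prediction cannot err against an empty
  # reference); required because lesion-free slices are legitimate input.
  switch(which,
    dsc = if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn),
    jaccard = if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn),
    sensitivity = if (tp + fn == 0) 1 else tp / (tp + fn),
    precision = if (tp + fp == 0) 1 else tp / (tp + fp),
    accuracy = (tp + tn) / (tp + fp + fn + tn)
  )
}

#' Dice similarity coefficient
#'
#' `2 TP / (2 TP + FP + FN)`; returns 1 when both masks are empty.
#' @inheritParams confusion_counts
#' @return fraction in `[0, 1]`.
#' @export
dsc <- function(pred, truth) metric_from_counts(confusion_counts(pred, truth), "dsc")

#' Jaccard index
#'
#' `TP / (TP + FP + FN)`; 1 when both masks are empty. Related to the Dice
#' coefficient by `J = D / (2 - D)` on any pooled pair.
#' @inheritParams confusion_counts
#' @return fraction in `[0, 1]`.
#' @export
jaccard <- function(pred, truth) metric_from_counts(confusion_counts(pred, truth), "jaccard")

#' Sensitivity (recall)
#'
#' `TP / (TP + FN)`; 1 when the truth mask is empty.
#' @inheritParams confusion_counts
#' @return fraction in `[0, 1]`.
#' @export
sensitivity <- function(pred, truth) metric_from_counts(confusion_counts(pred, truth), "sensitivity")

#' Precision (positive predictive value)
#'
#' `TP / (TP + FP)`; 1 when the prediction mask is empty.
#' @inheritParams confusion_counts
#' @return fraction in `[0, 1]`.
#' @export
precision <- function(pred, truth) metric_from_counts(confusion_counts(pred, truth), "precision")

#' Pixel accuracy
#'
#' `(TP + TN) / total`.
#' @inheritParams confusion_counts
#' @return fraction in `[0, 1]`.
#' @export
pixel_accuracy <- function(pred, truth) metric_from_counts(confusion_counts(pred, truth), "accuracy")

#' Segmentation metrics over a set of slices
#'
#' Computes DSC, Jaccard, sensitivity, precision and accuracy over paired
#' prediction/truth masks. Under `"global-pooled"` aggregation the
#' confusion counts are summed over slices before the metrics are formed
#' (making the Dice--Jaccard identity exact); `"per-slice-mean"` averages
#' per-slice metrics instead.
#'
#' @param preds,truths lists of binary masks (or single masks).
#' @param aggregation `"global-pooled"` or `"per-slice-mean"`.
#' @param fold_id optional fold provenance.
#' @return object of class `metrics_report`: a one-row data frame with
#'   columns `dsc`, `jaccard`, `sensitivity`, `precision`, `accuracy`,
#'   `n_slices`, `fold_id`, `aggregation`.
#' @export
metrics_report <- function(preds, truths,
                           aggregation = c("global-pooled", "per-slice-mean"),
                           fold_id = NA_integer_) {
  aggregation <- match.arg(aggregation)
  if (is.matrix(preds)) preds <- list(preds)
  if (is.matrix(truths)) truths <- list(truths)
  if (length(preds) != length(truths)) stop_input("preds/truths length mismatch")
  nms <- c("dsc", "jaccard", "sensitivity", "precision", "accuracy")
  if (aggregation == "global-pooled") {
    cc <- Reduce(`+`, Map(confusion_counts, preds, truths))
    vals <- vapply(nms, function(m) metric_from_counts(cc, m), numeric(1))
  } else {
    per <- vapply(seq_along(preds), function(i) {
      cc <- confusion_counts(preds[[i]], truths[[i]])
      vapply(nms, function(m) metric_from_counts(cc, m), numeric(1))
    }, numeric(length(nms)))
    vals <- rowMeans(matrix(per, nrow = length(nms)))
    names(vals) <- nms
  }
  out <- as.data.frame(as.list(vals))
  out$n_slices <- length(preds)
  out$fold_id <- fold_id
  out$aggregation <- aggregation
  class(out) <- c("metrics_report", class(out))
  out
}

#' ROC curve and AUC for node-level lesion probabilities
#'
#' Standard threshold sweep (via pROC); the AUC is invariant under any
#' strictly monotone transform of the probabilities and equals the
#' Mann-Whitney U statistic divided by `n1 * n0`.
#'
#' @param node_probs lesion probabilities in `[0, 1]`.
#' @param node_labels binary labels; both classes must be present.
#' @return list with `fpr`, `tpr`, `thresholds` (sorted by threshold) and
#'   `auc`.
#' @export
roc_curve <- function(node_probs, node_labels) {
  if (length(node_probs) != length(node_labels)) stop_input("length mismatch")
  if (any(node_probs < 0 | node_probs > 1)) stop_input("probabilities must be in [0, 1]")
  if (!all(node_labels %in% c(0, 1))) stop_input("labels must be binary")
  for (cls in 0:1)
    if (!any(node_labels == cls))
      stop_input("class ", cls, " is absent; ROC needs both classes")
  r <- pROC::roc(response = node_labels, predictor = node_probs,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  ord <- order(r$thresholds)
  list(fpr = 1 - r$specificities[ord], tpr = r$sensitivities[ord],
       thresholds = r$thresholds[ord], auc = as.numeric(r$auc))
}

#' Paired fold-wise significance tests
#'
#' Two-sided paired t-test and Wilcoxon signed-rank test on per-fold metric
#' values of two methods/conditions. Degenerate inputs are flagged rather
#' than failing: identical vectors (all differences zero) return the
#' sentinel `p = 1` for both tests with `degenerate = "identical"`;
#' constant non-zero differences leave the t-test undefined
#' (`t_p = NA`, `degenerate = "zero-variance"`).
#'
#' @param metric_a,metric_b equal-length (`>= 5`) paired per-fold metrics.
#' @return list with `t_p`, `wilcoxon_p`, `degenerate` (`"none"`,
#'   `"identical"` or `"zero-variance"`).
#' @export
fold_significance <- function(metric_a, metric_b) {
  if (length(metric_a) != length(metric_b)) stop_input("paired vectors differ in length")
  if (length(metric_a) < 5) stop_input("need at least 5 paired folds")
  d <- metric_a - metric_b
  if (all(d == 0))
    return(list(t_p = 1, wilcoxon_p = 1, degenerate = "identical"))
  if (stats::sd(d) == 0)
    return(list(t_p = NA_real_,
                wilcoxon_p = suppressWarnings(
                  wilcox.test(metric_a, metric_b, paired = TRUE, exact = FALSE)$p.value),
                degenerate = "zero-variance"))
  list(t_p = t.test(metric_a, metric_b, paired = TRUE)$p.value,
       wilcoxon_p = suppressWarnings(
         wilcox.test(metric_a, metric_b, paired = TRUE, exact = FALSE)$p.value),
       degenerate = "none")
}
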