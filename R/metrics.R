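## Classifier evaluation: AUC, Youden threshold, confusion metrics,
## bootstrap confidence intervals, matched-patch correlation.

check_two_classes <- function(labels) {
  if (!all(labels %in% c(0, 1))) stopf("labels must be 0 or 1")
  if (length(unique(labels)) < 2L)
    stopf("both classes must be present")
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney concordance probability via midranks,
#' so ties count one half.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels 0/1 labels, both classes present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  check_two_classes(labels)
  r <- rank(scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Operating threshold maximizing Youden's J
#'
#' Evaluates `J = sensitivity + specificity - 1` at every observed score
#' as a candidate threshold (predict positive when `score >= t`) and
#' returns the smallest candidate achieving the maximum.
#'
#' @inheritParams roc_auc
#' @return The selected threshold.
#' @export
youden_threshold <- function(scores, labels) {
  check_two_classes(labels)
  cand <- sort(unique(scores))
  j <- vapply(cand, function(t) {
    pred <- scores >= t
    sens <- sum(pred & labels == 1) / sum(labels == 1)
    spec <- sum(!pred & labels == 0) / sum(labels == 0)
    sens + spec - 1
  }, 0)
  cand[which(j >= max(j) - 1e-12)[1]]
}

#' Confusion-matrix metrics at a threshold
#'
#' Predictions are `score >= threshold`.  MCC returns 0 when any factor
#' of its denominator is zero.
#'
#' @inheritParams roc_auc
#' @param threshold finite operating threshold.
#' @return List with `accuracy`, `sensitivity`, `specificity`, `f1`,
#'   `mcc`, `threshold` and the confusion counts.
#' @export
confusion_metrics <- function(scores, labels, threshold) {
  if (!is.finite(threshold)) stopf("threshold must be finite")
  if (!all(labels %in% c(0, 1))) stopf("labels must be 0 or 1")
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1); tn <- sum(!pred & labels == 0)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  list(accuracy = (tp + tn) / length(labels),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn)
            else NA_real_,
       mcc = if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den),
       threshold = threshold, tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Percentile bootstrap confidence interval for the AUC
#'
#' Case resampling with replacement at the slide level; resamples
#' missing a class are redrawn.  The 95% interval takes the 2.5 and
#' 97.5 percentiles of the resampled AUCs.
#'
#' @inheritParams roc_auc
#' @param n_resamples number of bootstrap resamples (default 2000; a
#'   warning is issued below 100).
#' @param seed RNG seed.
#' @param conf confidence level (default 0.95).
#' @return Numeric `c(low, high)`.
#' @export
bootstrap_ci <- function(scores, labels, n_resamples = 2000L, seed = 1L,
                         conf = 0.95) {
  check_two_classes(labels)
  if (n_resamples < 100L)
    warnf("only %d bootstrap resamples; interval will be unstable",
          n_resamples)
  n <- length(scores)
  aucs <- with_seed(seed, vapply(seq_len(n_resamples), function(i) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[idx])) == 2L) break
    }
    roc_auc(scores[idx], labels[idx])
  }, 0))
  a <- (1 - conf) / 2
  unname(quantile(aucs, c(a, 1 - a), type = 7))
}

#' Full metrics report for slide-level predictions
#'
#' AUC with a bootstrap confidence interval plus accuracy, sensitivity,
#' specificity, F1 and MCC at the Youden-optimal threshold.
#'
#' @inheritParams bootstrap_ci
#' @return An object of class `milts_metrics`.
#' @export
metrics_report <- function(scores, labels, n_resamples = 2000L,
                           seed = 1L) {
  thr <- youden_threshold(scores, labels)
  cm <- confusion_metrics(scores, labels, thr)
  ci <- bootstrap_ci(scores, labels, n_resamples, seed)
  structure(c(list(auc = roc_auc(scores, labels),
                   ci_low = ci[1], ci_high = ci[2],
                   n = length(labels)), cm),
            class = "milts_metrics")
}

#' @export
print.milts_metrics <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f), n = %d\n",
              x$auc, x$ci_low, x$ci_high, x$n))
  cat(sprintf("Youden threshold %.3f: accuracy %.3f, sensitivity %.3f, ",
              x$threshold, x$accuracy, x$sensitivity))
  cat(sprintf("specificity %.3f, F1 %.3f, MCC %.3f\n",
              x$specificity, x$f1, x$mcc))
  invisible(x)
}

#' Correlation between predictions and a paired quantification grid
#'
#' Emulates validation against a spatially matched reference (e.g. a
#' stain-quantification grid on the same patch lattice): the
#' `ceiling(fraction * N)` patches with the highest predicted
#' probability are selected, together with an equal-sized set of the
#' lowest-predicted patches (`mode = "symmetric"`, the default, which
#' keeps the correlation well defined when the reference is nearly
#' constant within one tail), and the Pearson correlation between
#' prediction and reference over the selection is returned.
#'
#' @param pred numeric vector/matrix of predicted probabilities per
#'   patch.
#' @param reference numeric vector/matrix of reference quantifications,
#'   same length.
#' @param fraction fraction of patches per tail, in `(0, 1]`.
#' @param mode `"symmetric"` (top + bottom) or `"top"` (top only).
#' @return Pearson correlation coefficient.
#' @export
matched_patch_correlation <- function(pred, reference, fraction = 0.01,
                                      mode = c("symmetric", "top")) {
  mode <- match.arg(mode)
  pred <- as.vector(pred); reference <- as.vector(reference)
  if (length(pred) != length(reference))
    stopf("pred and reference grids are not aligned")
  if (fraction <= 0 || fraction > 1) stopf("fraction must be in (0, 1]")
  n <- length(pred)
  k <- ceiling(fraction * n)
  ord <- order(pred, decreasing = TRUE)
  sel <- ord[seq_len(k)]
  if (mode == "symmetric")
    sel <- union(sel, rev(ord)[seq_len(k)])
  if (length(sel) < 3L)
    stopf("fewer than 3 patches selected; increase fraction")
  cor(pred[sel], reference[sel])
}
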