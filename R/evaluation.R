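#' Confusion matrix (rows = predicted, columns = truth)
#'
#' @param predicted,truth Equal-length vectors of class labels.
#' @param labels Declared label set; values outside it are an error.
#' @return Integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(predicted, truth,
                             labels = sort(unique(c(predicted, truth)))) {
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length")
  if (!length(predicted)) stop("empty input")
  bad <- setdiff(unique(c(predicted, truth)), labels)
  if (length(bad))
    stop("label(s) outside declared set: ", paste(bad, collapse = ", "))
  m <- table(factor(predicted, levels = labels),
             factor(truth, levels = labels))
  m <- unclass(as.matrix(m))
  dimnames(m) <- list(predicted = labels, truth = labels)
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Build a confusion matrix directly from counts
#'
#' @param counts k x k matrix of counts (rows predicted, columns truth).
#' @param labels Class labels.
#' @export
confusion_from_counts <- function(counts, labels) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == ncol(counts), nrow(counts) == length(labels))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(predicted = labels, truth = labels)
  structure(counts, class = c("confusion_matrix", "matrix"))
}

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' Beta-quantile form: `lo = qbeta(a/2, x, n-x+1)`,
#' `hi = qbeta(1-a/2, x+1, n-x)`, with `lo = 0` at `x = 0` and `hi = 1`
#' at `x = n`.
#'
#' @param successes,n Counts with `0 <= successes <= n`, `n >= 1`.
#' @param level Confidence level (default 0.95).
#' @return Numeric `c(lo, hi)`.
#' @export
clopper_pearson_ci <- function(successes, n, level = 0.95) {
  if (n < 1 || successes < 0 || successes > n ||
      successes != round(successes) || n != round(n))
    stop("need integer counts with 0 <= successes <= n, n >= 1")
  a <- 1 - level
  lo <- if (successes == 0) 0 else
    stats::qbeta(a / 2, successes, n - successes + 1)
  hi <- if (successes == n) 1 else
    stats::qbeta(1 - a / 2, successes + 1, n - successes)
  c(lo = lo, hi = hi)
}

#' Sensitivity, specificity, PPV and NPV with exact CIs
#'
#' One-vs-rest collapse of a confusion matrix for `positive_class`:
#' TP is the diagonal cell, FN the rest of the positive column, FP the rest
#' of the positive row, TN everything else. Each proportion carries a
#' Clopper-Pearson 95% CI; a zero denominator yields `NA` (undefined), not
#' zero.
#'
#' @param cm A [confusion_matrix()].
#' @param positive_class Label treated as positive.
#' @param level CI level (default 0.95).
#' @return List of class `binary_metrics`; each element is
#'   `c(estimate, lo, hi)`. Also carries the collapsed counts.
#' @export
binary_metrics <- function(cm, positive_class, level = 0.95) {
  labs <- rownames(cm)
  if (!positive_class %in% labs)
    stop("positive_class '", positive_class, "' not among labels")
  i <- match(positive_class, labs)
  tp <- cm[i, i]
  fn <- sum(cm[-i, i, drop = FALSE])
  fp <- sum(cm[i, -i, drop = FALSE])
  tn <- sum(cm[-i, -i, drop = FALSE])
  binary_metrics_counts(tp, fn, fp, tn, level = level)
}

#' @rdname binary_metrics
#' @param tp,fn,fp,tn Collapsed 2x2 counts.
#' @export
binary_metrics_counts <- function(tp, fn, fp, tn, level = 0.95) {
  prop <- function(x, n) {
    if (n == 0) return(c(estimate = NA_real_, lo = NA_real_, hi = NA_real_))
    c(estimate = x / n, clopper_pearson_ci(x, n, level))
  }
  structure(list(
    sensitivity = prop(tp, tp + fn),
    specificity = prop(tn, tn + fp),
    ppv = prop(tp, tp + fp),
    npv = prop(tn, tn + fn),
    counts = c(tp = tp, fn = fn, fp = fp, tn = tn)),
    class = "binary_metrics")
}

#' @export
print.binary_metrics <- function(x, ...) {
  for (m in c("sensitivity", "specificity", "ppv", "npv")) {
    v <- x[[m]]
    if (is.na(v[1])) cat(sprintf("  %-12s undefined\n", m))
    else cat(sprintf("  %-12s %6.2f%% (%.2f-%.2f%%)\n", m,
                     100 * v[1], 100 * v[2], 100 * v[3]))
  }
  invisible(x)
}

#' ROC curve and AUC
#'
#' Scores are swept over all observed thresholds with the rule
#' "positive iff score > threshold". The AUC equals the Mann-Whitney
#' U-statistic normalized by `n1 * n0` (ties counted 1/2), which the
#' test-suite verifies against a brute-force pairwise oracle; it is also
#' the trapezoidal area under the swept curve.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Logical or 0/1 truth (TRUE/1 = positive).
#' @return List of class `roc_result`: `thresholds`, `tpr`, `fpr`, `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  if (any(is.na(scores)) || any(is.na(labels))) stop("NA in scores/labels")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  uniq <- sort(unique(scores))
  # candidate cutoffs: below all scores, midpoints, above all scores
  thr <- c(uniq[1] - 1, if (length(uniq) > 1) (uniq[-1] + uniq[-length(uniq)]) / 2,
           uniq[length(uniq)] + 1)
  tpr <- vapply(thr, function(t) sum(scores > t & labels) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores > t & !labels) / n0, numeric(1))
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_result")
}

#' Youden-optimal cutoff
#'
#' The threshold maximizing Youden's J = TPR - FPR; ties are broken toward
#' the higher threshold (higher specificity). Returned thresholds are
#' midpoints between adjacent observed scores, so for separable score
#' distributions the cutoff sits strictly inside the gap.
#'
#' @param roc A [roc_auc()] result.
#' @return Numeric cutoff (classification rule: score > cutoff).
#' @export
optimal_cutoff_youden <- function(roc) {
  j <- roc$tpr - roc$fpr
  best <- which(j >= max(j) - 1e-12)
  roc$thresholds[max(best)]
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> AUC =", format(x$auc, digits = 4), "over",
      length(x$thresholds), "thresholds\n")
  invisible(x)
}
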