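test_that("confusion matrices count predicted x truth", {
  cm <- confusion_matrix(c("a", "b", "a"), c("a", "b", "a"),
                         labels = c("a", "b"))
  expect_equal(unclass(cm)[1, 1], 2L)
  expect_equal(sum(cm), 3L)
  expect_equal(sum(cm[row(cm) != col(cm)]), 0L)
  expect_error(confusion_matrix(character(), character()), "empty")
  expect_error(confusion_matrix("a", "c", labels = c("a", "b")),
               "outside declared")
})

test_that("the published 4x4 tissue matrix reconstructs from its pairs", {
  counts <- matrix(c(14, 5, 2, 2,
                     0, 0, 2, 1,
                     1, 1, 8, 1,
                     0, 1, 0, 4), 4, 4, byrow = TRUE)
  labels <- c("breast", "gastric", "liver", "lymphoma")
  predicted <- character(0); truth <- character(0)
  for (i in 1:4) for (j in 1:4) {
    predicted <- c(predicted, rep(labels[i], counts[i, j]))
    truth <- c(truth, rep(labels[j], counts[i, j]))
  }
  cm <- confusion_matrix(predicted, truth, labels)
  expect_identical(unname(unclass(cm)), matrix(as.integer(counts), 4, 4))
  expect_identical(cm, confusion_from_counts(counts, labels))
  expect_equal(sum(cm), 42L)
})

test_that("Clopper-Pearson intervals are exact beta quantiles", {
  ci <- clopper_pearson_ci(36, 42)
  expect_equal(round(100 * ci[["lo"]], 2), 71.46)
  expect_equal(round(100 * ci[["hi"]], 2), 94.57)
  expect_equal(clopper_pearson_ci(0, 10)[["lo"]], 0)
  expect_equal(clopper_pearson_ci(10, 10)[["hi"]], 1)
  expect_error(clopper_pearson_ci(11, 10), "0 <= successes")
})

test_that("CP coverage on simulated binomials is >= nominal", {
  set.seed(29)
  n <- 50; p <- 0.8
  x <- rbinom(2000, n, p)
  lo <- ifelse(x == 0, 0, qbeta(0.025, x, n - x + 1))
  hi <- ifelse(x == n, 1, qbeta(0.975, x + 1, n - x))
  covered <- mean(lo <= p & p <= hi)
  expect_gte(covered, 0.95)
  # and our implementation agrees with the direct quantile form
  idx <- sample(2000, 50)
  for (i in idx)
    expect_equal(unname(clopper_pearson_ci(x[i], n)),
                 c(lo[i], hi[i]))
})

test_that("binary metrics reproduce the published screening table", {
  # training set: TP 36, FN 6, FP 58, TN 236
  tr <- binary_metrics_counts(36, 6, 58, 236)
  expect_equal(round(100 * tr$sensitivity[["estimate"]], 2), 85.71)
  expect_equal(round(100 * tr$specificity[["estimate"]], 2), 80.27)
  expect_equal(round(100 * tr$ppv[["estimate"]], 1), 38.3)
  expect_equal(round(100 * tr$npv[["estimate"]], 2), 97.52)
  # validation set: TP 17, FN 3, FP 28, TN 112
  va <- binary_metrics_counts(17, 3, 28, 112)
  expect_equal(100 * va$sensitivity[["estimate"]], 85)
  expect_equal(100 * va$specificity[["estimate"]], 80)
  expect_equal(round(100 * va$ppv[["estimate"]], 2), 37.78)
  expect_equal(round(100 * va$npv[["estimate"]], 2), 97.39)
  # all-correct classifier -> every metric 1
  all_right <- binary_metrics_counts(10, 0, 0, 20)
  for (m in c("sensitivity", "specificity", "ppv", "npv"))
    expect_equal(all_right[[m]][["estimate"]], 1)
  # zero denominator -> undefined, not zero
  und <- binary_metrics_counts(0, 0, 5, 10)
  expect_true(is.na(und$sensitivity[["estimate"]]))
})

test_that("one-vs-rest collapse matches the published breast column", {
  counts <- matrix(c(14, 5, 2, 2,
                     0, 0, 2, 1,
                     1, 1, 8, 1,
                     0, 1, 0, 4), 4, 4, byrow = TRUE)
  cm <- confusion_from_counts(counts, c("breast", "gastric", "liver",
                                        "lymphoma"))
  b <- binary_metrics(cm, "breast")
  expect_equal(unname(b$counts), c(14, 1, 9, 18))
  expect_equal(round(100 * b$sensitivity[["estimate"]], 2), 93.33)
  expect_equal(round(100 * b$specificity[["estimate"]], 2), 66.67)
  expect_equal(round(100 * b$ppv[["estimate"]], 2), 60.87)
  expect_equal(round(100 * b$npv[["estimate"]], 2), 94.74)
})

test_that("AUC equals the normalized U-statistic with ties at 1/2", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12),
                       c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))$auc, 1)
  expect_equal(roc_auc(rep(5, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)
  set.seed(13)
  scores <- round(rnorm(30), 1)     # rounding forces ties
  labels <- runif(30) < 0.4
  r <- roc_auc(scores, labels)
  expect_equal(r$auc, oracle_auc(scores, labels), tolerance = 1e-12)
  # invariance under strictly monotone transforms
  expect_equal(roc_auc(exp(scores), labels)$auc, r$auc)
  expect_equal(roc_auc(rank(scores, ties.method = "average"), labels)$auc,
               r$auc)
  # TPR/FPR monotone along the sweep
  expect_true(all(diff(r$tpr) <= 0))
  expect_true(all(diff(r$fpr) <= 0))
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("Youden cutoff sits in the gap, ties break upward", {
  r <- roc_auc(c(1, 2, 3, 10, 11, 12),
               c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  cut <- optimal_cutoff_youden(r)
  expect_gt(cut, 3); expect_lt(cut, 10)
  # equal-J tie: thresholds 1.5 and 3.5 both give J = 0.5
  r2 <- roc_auc(c(1, 2, 3, 4), c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(optimal_cutoff_youden(r2), 3.5)
  # two equal-variance Gaussians: optimal cutoff at the midpoint
  set.seed(17)
  scores <- c(rnorm(4000, 0), rnorm(4000, 2))
  labels <- rep(c(FALSE, TRUE), each = 4000)
  cut3 <- optimal_cutoff_youden(roc_auc(scores, labels))
  expect_equal(cut3, 1, tolerance = 0.15)
})
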