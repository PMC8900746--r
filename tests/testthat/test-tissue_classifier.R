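make_subject <- function(seed = 1) {
  set.seed(seed)
  npcc <- structure(list(
    r_raw = c(BRCA = -0.2, DLBC = -0.3, LIHC = -0.5),
    npcc = c(BRCA = 0.2, DLBC = 0.3, LIHC = 0.5), n_genes_used = 100L),
    class = "npcc_vector")
  z <- random_z()
  ptm <- ptm_panel(default_ptm_cutoffs() * runif(7, 0.2, 1.5))
  list(npcc = npcc, z = z, ptm = ptm)
}

test_that("feature vectors assemble in canonical 32-feature order", {
  s <- make_subject(1)
  fv <- assemble_features(s$npcc, s$z, s$ptm)
  expect_length(fv, 32L)
  expect_identical(names(fv), classifier_feature_names())
  # hand-assembled oracle
  manual <- c(s$npcc$npcc[c("BRCA", "DLBC", "LIHC")],
              s$z[paste0("chr", 1:22)],
              s$ptm[names(default_ptm_cutoffs())])
  expect_equal(unname(fv), unname(manual))
  # permuted input field order canonicalizes identically
  fv2 <- assemble_features(
    s$npcc$npcc[c("LIHC", "BRCA", "DLBC")],
    chrom_zscores(s$z[sample(names(s$z))]),
    ptm_panel(s$ptm[rev(names(s$ptm))]))
  expect_identical(fv2, fv)
  # chrX/chrY never enter the feature vector
  expect_false(any(grepl("chrX|chrY", names(fv))))
})

test_that("missing components error by name, no imputation", {
  s <- make_subject(2)
  expect_error(assemble_features(NULL, s$z, s$ptm), "npcc")
  expect_error(assemble_features(s$npcc, NULL, s$ptm), "z-scores")
  expect_error(assemble_features(s$npcc, s$z, NULL), "ptm")
  expect_error(assemble_features(s$npcc$npcc[c("BRCA", "DLBC")], s$z, s$ptm),
               "LIHC")
})

# well-separated classes: each class elevates its own block of 8 features,
# so informative splits are available at every node (a lone marker feature
# drowned in noise columns defeats any reference forest at this n)
separable_data <- function(n_per_class, seed = 1) {
  set.seed(seed)
  k <- 4
  labels <- rep(c("breast", "gastric", "liver", "lymphoma"),
                each = n_per_class)
  x <- matrix(rnorm(length(labels) * 32, sd = 0.5), ncol = 32)
  for (i in seq_len(k)) {
    rows <- ((i - 1) * n_per_class + 1):(i * n_per_class)
    x[rows, ((i - 1) * 8 + 1):(i * 8)] <-
      x[rows, ((i - 1) * 8 + 1):(i * 8)] + 10
  }
  colnames(x) <- classifier_feature_names()
  list(x = x, labels = labels)
}

test_that("training is deterministic, separable data fits perfectly", {
  d <- separable_data(10, seed = 4)
  fit <- train_classifier(d$x, d$labels, ntree = 100, seed = 7)
  expect_equal(predict(fit, d$x, type = "class"), d$labels)
  p1 <- predict(fit, d$x)
  expect_true(all(abs(rowSums(p1) - 1) < 1e-12))
  fit2 <- train_classifier(d$x, d$labels, ntree = 100, seed = 7)
  expect_identical(p1, predict(fit2, d$x))
  expect_error(train_classifier(d$x, rep("breast", nrow(d$x))),
               ">= 2 classes")
})

test_that("LOOCV holds each subject out and is perfect when separable", {
  d <- separable_data(3, seed = 5)   # n = 12
  cv <- loocv(d$x, d$labels, ntree = 100, seed = 5)
  expect_equal(cv$accuracy, 1)
  expect_equal(nrow(cv$prob), 12L)
  expect_true(all(abs(rowSums(cv$prob) - 1) < 1e-12))
  expect_error(loocv(d$x[1:6, ], d$labels[1:6]), ">= 8")
})

test_that("pure-noise LOOCV sits at chance level across seeds", {
  accs <- vapply(1:8, function(s) {
    set.seed(s)
    x <- matrix(rnorm(40 * 32), ncol = 32)
    colnames(x) <- classifier_feature_names()
    labels <- rep(c("breast", "gastric", "liver", "lymphoma"), each = 10)
    loocv(x, labels, ntree = 100, seed = s)$accuracy
  }, numeric(1))
  # LOOCV at chance is pessimistically biased below 1/k; wide a-priori band
  expect_gt(mean(accs), 0.25 - 0.10)
  expect_lt(mean(accs), 0.25 + 0.10)
})

test_that("Gini importance ranks an informative feature first", {
  set.seed(6)
  x <- matrix(rnorm(200 * 8), ncol = 8)
  labels <- ifelse(x[, 3] > 0, "a", "b")
  fit <- rf_train(x, labels, ntree = 200, seed = 6)
  imp <- feature_importance(fit)
  expect_equal(nrow(imp), 8L)
  expect_equal(imp$feature[1], "V3")
  expect_true(all(diff(imp$mean_decrease_gini) <= 0))

  # all-noise: importance spread with no dominant feature
  xn <- matrix(rnorm(200 * 8), ncol = 8)
  ln <- sample(c("a", "b"), 200, TRUE)
  fitn <- rf_train(xn, ln, ntree = 200, seed = 6)
  impn <- feature_importance(fitn)
  expect_lt(impn$mean_decrease_gini[1],
            3 * median(impn$mean_decrease_gini))
  # 32-feature model reports 32 entries
  d <- separable_data(5, seed = 7)
  expect_equal(nrow(feature_importance(
    train_classifier(d$x, d$labels, ntree = 50, seed = 1))), 32L)
})
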