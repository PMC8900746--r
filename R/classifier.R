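#' Canonical 32-feature order of the tissue-of-origin classifier
#'
#' Three NPCC values (BRCA, DLBC, LIHC), z-scores of the 22 autosomes
#' (chr19 included: its exclusion applies only to MTOP5Zscores; chrX/chrY
#' excluded), and the seven plasma tumor marker concentrations.
#'
#' @return Character vector of 32 feature names.
#' @export
classifier_feature_names <- function() {
  c(paste0("npcc_", c("BRCA", "DLBC", "LIHC")),
    paste0("z_", autosome_names()),
    names(default_ptm_cutoffs()))
}

#' Assemble one subject's 32-feature vector
#'
#' Deterministic canonical ordering regardless of input field order.
#' Any missing component is an error naming it: subjects without a PTM
#' panel are excluded from classification, never imputed.
#'
#' @param npcc An `npcc_vector` (or named numeric over BRCA/DLBC/LIHC).
#' @param z A [chrom_zscores()].
#' @param ptm A [ptm_panel()].
#' @return Named numeric vector of length 32 in canonical order.
#' @export
assemble_features <- function(npcc, z, ptm) {
  if (missing(npcc) || is.null(npcc)) stop("missing component: npcc")
  if (missing(z) || is.null(z)) stop("missing component: z-scores")
  if (missing(ptm) || is.null(ptm)) stop("missing component: ptm")
  npcc_v <- if (inherits(npcc, "npcc_vector")) npcc$npcc else npcc
  types <- c("BRCA", "DLBC", "LIHC")
  if (!all(types %in% names(npcc_v)))
    stop("missing component: npcc values for ",
         paste(setdiff(types, names(npcc_v)), collapse = ", "))
  if (!all(autosome_names() %in% names(z)))
    stop("missing component: z-scores for ",
         paste(setdiff(autosome_names(), names(z)), collapse = ", "))
  markers <- names(default_ptm_cutoffs())
  if (!all(markers %in% names(ptm)))
    stop("missing component: PTM ",
         paste(setdiff(markers, names(ptm)), collapse = ", "))
  out <- c(as.numeric(npcc_v[types]),
           as.numeric(z[autosome_names()]),
           as.numeric(ptm[markers]))
  names(out) <- classifier_feature_names()
  if (any(!is.finite(out))) stop("non-finite feature values")
  out
}

#' Train the tissue-of-origin random forest
#'
#' ntree = 500 and mtry = floor(sqrt(32)) = 5 by default, matching the
#' reference classification defaults.
#'
#' @param features Numeric matrix, rows = subjects, 32 canonical columns
#'   (or any consistent feature set).
#' @param labels Cancer-type labels.
#' @param ntree,mtry,seed Forest parameters.
#' @return An `mcanary_rf`.
#' @export
train_classifier <- function(features, labels, ntree = 500L,
                             mtry = floor(sqrt(ncol(features))), seed = 1L) {
  rf_train(as.matrix(features), labels, ntree = ntree, mtry = mtry,
           seed = seed)
}

#' Leave-one-out cross-validation of the classifier
#'
#' Each subject is predicted by a forest trained on all other subjects.
#' Folds are re-seeded deterministically (`seed + fold`), so the whole
#' procedure is reproducible.
#'
#' @param features Numeric matrix (rows = subjects).
#' @param labels Class labels.
#' @param ntree,mtry,seed Forest parameters.
#' @return List of class `loocv_result`: `prob` (n x k matrix of held-out
#'   probabilities), `predicted`, `truth`, `accuracy`.
#' @export
loocv <- function(features, labels, ntree = 500L,
                  mtry = floor(sqrt(ncol(features))), seed = 1L) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 8L) stop("LOOCV needs >= 8 subjects, got ", n)
  labels <- factor(labels)
  prob <- matrix(NA_real_, n, nlevels(labels),
                 dimnames = list(rownames(features), levels(labels)))
  for (i in seq_len(n)) {
    fit <- train_classifier(features[-i, , drop = FALSE], labels[-i],
                            ntree = ntree, mtry = mtry, seed = seed + i)
    p <- predict(fit, features[i, , drop = FALSE], type = "prob")
    prob[i, colnames(p)] <- p[1L, ]
  }
  prob[is.na(prob)] <- 0  # classes absent from a training fold get no votes
  predicted <- colnames(prob)[max.col(prob, ties.method = "first")]
  structure(list(prob = prob, predicted = predicted,
                 truth = as.character(labels),
                 accuracy = mean(predicted == as.character(labels))),
            class = "loocv_result")
}

#' Per-class ROC/AUC from LOOCV probabilities
#'
#' One-vs-rest AUC for each class, using the held-out class probability as
#' the score.
#'
#' @param cv A [loocv()] result.
#' @return Named numeric vector of AUCs.
#' @export
loocv_class_auc <- function(cv) {
  vapply(colnames(cv$prob), function(cl)
    roc_auc(cv$prob[, cl], cv$truth == cl)$auc, numeric(1))
}

#' Ranked Gini feature importance
#'
#' @param model An `mcanary_rf`.
#' @return data.table (feature, mean_decrease_gini) in descending order.
#' @export
feature_importance <- function(model) {
  imp <- model$importance
  data.table::data.table(
    feature = names(imp)[order(-imp)],
    mean_decrease_gini = unname(sort(imp, decreasing = TRUE)))
}

#' @export
print.loocv_result <- function(x, ...) {
  cat("<loocv_result> n =", nrow(x$prob), ", accuracy =",
      format(x$accuracy, digits = 3), "\n")
  invisible(x)
}
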