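#' Random forest classifier backend
#'
#' Bagged classification forest with Gini splitting, grown to purity
#' (nodesize 1) on bootstrap samples, `mtry` features tried per node.
#' Class probabilities are vote fractions over the `ntree` trees and
#' variable importance is the per-tree mean of the total Gini-impurity
#' decrease attributable to each feature (MeanDecreaseGini). Fully
#' deterministic given `seed`.
#'
#' @param x Numeric feature matrix (rows = samples).
#' @param y Class labels (factor or character).
#' @param ntree Number of trees (default 500).
#' @param mtry Features tried per split (default `floor(sqrt(ncol(x)))`).
#' @param seed Integer RNG seed.
#' @return List of class `mcanary_rf` with the fitted forest, class
#'   `levels`, `importance` (named by feature) and the call parameters.
#' @export
rf_train <- function(x, y, ntree = 500L, mtry = floor(sqrt(ncol(x))),
                     seed = 1L) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("features must be finite (no imputation)")
  y <- factor(y)
  if (nlevels(y) < 2L) stop("need >= 2 classes to train a classifier")
  if (nrow(x) != length(y)) stop("x and y size mismatch")
  fit <- .rf_fit_cpp(x, as.integer(y) - 1L, nlevels(y),
                     as.integer(ntree), as.integer(mtry), as.double(seed))
  imp <- setNames(fit$importance,
                  colnames(x) %||% paste0("V", seq_len(ncol(x))))
  structure(list(forest = fit, levels = levels(y), importance = imp,
                 ntree = ntree, mtry = mtry, seed = seed,
                 n_features = ncol(x)),
            class = "mcanary_rf")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname rf_train
#' @param object A fitted `mcanary_rf`.
#' @param newdata Numeric feature matrix.
#' @param type `"prob"` for the vote-fraction matrix, `"class"` for the
#'   argmax label.
#' @param ... Unused.
#' @export
predict.mcanary_rf <- function(object, newdata,
                               type = c("prob", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features)
    stop("newdata has ", ncol(newdata), " features, model expects ",
         object$n_features)
  prob <- .rf_predict_cpp(object$forest, newdata)
  colnames(prob) <- object$levels
  if (type == "prob") return(prob)
  object$levels[max.col(prob, ties.method = "first")]
}

#' @export
print.mcanary_rf <- function(x, ...) {
  cat("<mcanary_rf> ntree =", x$ntree, ", mtry =", x$mtry,
      ", classes:", paste(x$levels, collapse = ", "), "\n")
  invisible(x)
}
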