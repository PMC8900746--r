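#' MTOP5Zscores: mean of the top five absolute chromosome z-scores
#'
#' The maternal-cancer predictor statistic: the mean of the five largest
#' absolute z-scores among the 22 candidate chromosomes (chr1-18, chr20-22,
#' chrX; chrY and chr19 are excluded, chr19 because of its technical
#' artifact rate in non-cancer NIPT samples). The score is the mean of the
#' *absolute* values: a signed mean would let deletions cancel
#' amplifications and could never cross the positive cutoff for
#' deletion-dominated cancers.
#'
#' @param z A [chrom_zscores()].
#' @param exclude Chromosomes excluded from the candidates (default
#'   `c("chr19", "chrY")`).
#' @return List of class `mtop5_result` with `score`, `contributing`
#'   (data.table of the five (chromosome, z) pairs in descending |z|;
#'   ties broken by canonical chromosome order), `call` (`NA` until
#'   [classify_mtop5()] is applied) and `cutoff_used`.
#' @export
#' @examples
#' z <- chrom_zscores(setNames(c(10, -8, 6, 4, 3, rep(0, 18)),
#'                    c("chr1", "chr2", "chr3", "chr4", "chr5",
#'                      paste0("chr", 6:22), "chrX")))
#' mtop5zscore(z)$score  # (10+8+6+4+3)/5 = 6.2
mtop5zscore <- function(z, exclude = c("chr19", "chrY")) {
  candidates <- intersect(mtop5_candidate_names(exclude), names(z))
  if (length(candidates) < 5L)
    stop("MTOP5Zscores needs >= 5 scorable chromosomes after exclusions, ",
         "got ", length(candidates))
  # canonical chromosome order makes the |z| tie-break deterministic
  candidates <- candidates[order(match(candidates, chromosome_names()))]
  absz <- abs(z[candidates])
  ord <- order(-absz, match(candidates, chromosome_names()))
  top <- ord[1:5]
  structure(list(
    score = mean(absz[top]),
    contributing = data.table::data.table(
      chrom = candidates[top], z = as.numeric(z[candidates[top]])),
    call = NA_character_,
    cutoff_used = NA_real_),
    class = "mtop5_result")
}

#' Classify a subject by the MTOP5Zscores cutoff
#'
#' Positive iff the score is strictly greater than the cutoff (default
#' 5.94, the published optimal cutoff); a score exactly at the cutoff is
#' negative.
#'
#' @param score Numeric score, or an `mtop5_result`.
#' @param cutoff Decision cutoff (default 5.94).
#' @return For a numeric score, `"positive"` or `"negative"`; for an
#'   `mtop5_result`, the result with `call` and `cutoff_used` filled in.
#' @export
classify_mtop5 <- function(score, cutoff = 5.94) {
  if (inherits(score, "mtop5_result")) {
    score$call <- classify_mtop5(score$score, cutoff)
    score$cutoff_used <- cutoff
    return(score)
  }
  if (!is.finite(score)) stop("MTOP5Zscores score must be finite")
  if (score > cutoff) "positive" else "negative"
}

#' @export
print.mtop5_result <- function(x, ...) {
  cat("<mtop5_result> score =", format(x$score, digits = 4))
  if (!is.na(x$call)) cat("  call =", x$call, "(cutoff", x$cutoff_used, ")")
  cat("\n  contributing:",
      paste(sprintf("%s (%.2f)", x$contributing$chrom, x$contributing$z),
            collapse = ", "), "\n")
  invisible(x)
}

#' Score a cohort of z-score sets
#'
#' @param zlist Named list of [chrom_zscores()].
#' @param cutoff MTOP5Zscores cutoff (default 5.94).
#' @return data.table with subject_id, score, call and the contributing
#'   chromosomes as a comma-separated string.
#' @export
mtop5_cohort <- function(zlist, cutoff = 5.94) {
  rows <- lapply(names(zlist), function(id) {
    r <- classify_mtop5(mtop5zscore(zlist[[id]]), cutoff)
    data.table::data.table(
      subject_id = id, score = r$score, call = r$call,
      top5 = paste(r$contributing$chrom, collapse = ","))
  })
  data.table::rbindlist(rows)
}
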