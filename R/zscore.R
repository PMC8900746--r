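#' Per-subject chromosome z-scores
#'
#' Named numeric vector over `chr1..chr22, chrX` and optionally `chrY`
#' (absent for pregnancies with a female fetus). All present values must be
#' finite.
#'
#' @param z Named numeric vector of z-scores.
#' @return A `chrom_zscores` object.
#' @export
chrom_zscores <- function(z) {
  if (is.null(names(z))) stop("z-scores must be named by chromosome")
  bad <- setdiff(names(z), chromosome_names())
  if (length(bad)) stop("unknown chromosome(s): ", paste(bad, collapse = ", "))
  required <- setdiff(chromosome_names(), "chrY")
  missing <- setdiff(required, names(z))
  if (length(missing))
    stop("missing z-score(s) for: ", paste(missing, collapse = ", "))
  if (any(!is.finite(z))) stop("z-scores must be finite")
  structure(as.numeric(z), names = names(z),
            class = c("chrom_zscores", "numeric"))
}

#' Per-chromosome fragment fractions
#'
#' Each chromosome's share of the total fragment count; the standard input
#' to NIPT-style z-scoring. Sums to 1 exactly on integer counts.
#'
#' @param fragments A [fragment_set()].
#' @return Named numeric vector over the declared genome's chromosomes.
#' @export
chromosome_fractions <- function(fragments) {
  if (nrow(fragments) == 0L) stop("cannot compute fractions of zero fragments")
  genome <- fragments_genome(fragments)
  counts <- table(factor(fragments$chrom, levels = names(genome)))
  setNames(as.numeric(counts) / nrow(fragments), names(genome))
}

#' Reference panel of chromosome-fraction means and SDs
#'
#' @param mean_fraction,sd_fraction Named numeric vectors over the scored
#'   chromosomes; `sd_fraction` must be strictly positive.
#' @param n_panel Number of panel samples (optional metadata).
#' @return A `reference_panel`.
#' @export
reference_panel <- function(mean_fraction, sd_fraction, n_panel = NA_integer_) {
  if (!identical(names(mean_fraction), names(sd_fraction)))
    stop("mean and sd fractions must cover identical chromosomes")
  if (any(!is.finite(mean_fraction)) || any(!is.finite(sd_fraction)))
    stop("panel statistics must be finite")
  if (any(sd_fraction <= 0))
    stop("panel sd_fraction must be > 0 for every chromosome (offending: ",
         names(sd_fraction)[which(sd_fraction <= 0)[1L]], ")")
  structure(list(mean_fraction = mean_fraction, sd_fraction = sd_fraction,
                 n_panel = n_panel),
            class = "reference_panel")
}

#' Build a reference panel from euploid samples' fractions
#'
#' @param fraction_matrix Matrix, rows = samples, columns = chromosomes.
#' @return A [reference_panel()].
#' @export
build_reference_panel <- function(fraction_matrix) {
  if (nrow(fraction_matrix) < 2L)
    stop("need >= 2 panel samples to estimate an SD")
  mu <- colMeans(fraction_matrix)
  sdv <- apply(fraction_matrix, 2L, stats::sd)
  reference_panel(mu, sdv, n_panel = nrow(fraction_matrix))
}

#' Compute chromosome z-scores against a reference panel
#'
#' `z_c = (f_c - mu_c) / sigma_c`. Chromosomes absent from the panel
#' (typically chrY in an all-female panel) are skipped.
#'
#' @param fractions Named chromosome fractions (see
#'   [chromosome_fractions()]).
#' @param panel A [reference_panel()].
#' @return A [chrom_zscores()].
#' @export
compute_zscores <- function(fractions, panel) {
  common <- intersect(names(fractions), names(panel$mean_fraction))
  if (!length(common)) stop("no chromosomes shared between sample and panel")
  z <- (fractions[common] - panel$mean_fraction[common]) /
    panel$sd_fraction[common]
  chrom_zscores(z)
}

#' Flag multiple chromosomal aneuploidies (MCA)
#'
#' MCA is defined as at least two chromosomes having absolute z-scores
#' strictly greater than the threshold (default 3.0). Ties at exactly the
#' threshold do not count. Chromosomes with no defined z (absent chrY) are
#' excluded from the count.
#'
#' @param z A [chrom_zscores()].
#' @param threshold Absolute z threshold (default 3.0).
#' @return Logical flag, with attribute `n_aberrant` (number of
#'   chromosomes over threshold).
#' @export
flag_mca <- function(z, threshold = 3.0) {
  n_ab <- sum(abs(z) > threshold)
  structure(n_ab >= 2L, n_aberrant = n_ab)
}
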