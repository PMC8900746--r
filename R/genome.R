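#' Chromosome naming conventions
#'
#' The pipeline works on the 24 human chromosomes `chr1..chr22, chrX, chrY`.
#' These helpers return the canonical name sets in canonical order.
#'
#' @return Character vector of chromosome names.
#' @export
chromosome_names <- function() {
  c(paste0("chr", 1:22), "chrX", "chrY")
}

#' @rdname chromosome_names
#' @export
autosome_names <- function() paste0("chr", 1:22)

#' Candidate chromosomes for the MTOP5Zscores statistic
#'
#' chrY and chr19 are excluded: chrY because it is absent in pregnancies with
#' a female fetus, chr19 because of its high technical artifact rate in
#' non-cancer NIPT samples (deletion 53.92%, amplification 21.89%).
#'
#' @param exclude Chromosomes to drop (default `c("chr19", "chrY")`).
#' @return Character vector of 22 candidate chromosome names.
#' @export
mtop5_candidate_names <- function(exclude = c("chr19", "chrY")) {
  setdiff(chromosome_names(), exclude)
}

#' Declare a genome as named chromosome lengths
#'
#' @param lengths Named integer vector, names are chromosome names, values
#'   are chromosome lengths in bp.
#' @return A validated named integer vector of class `mcanary_genome`.
#' @export
declare_genome <- function(lengths) {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths))))
    stop("genome lengths must be a named vector")
  if (anyDuplicated(names(lengths)))
    stop("duplicated chromosome names in genome")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromosome lengths must be positive and finite")
  structure(as.integer(lengths), names = names(lengths),
            class = "mcanary_genome")
}

#' Small synthetic genome used by the simulator and the test-suite
#'
#' Two autosomes (2 Mb + 1 Mb). Thirty 100-kb bins in total: large enough to
#' exercise copy-ratio binning and TSS windows, small enough that a full
#' fragment-level simulation runs in seconds.
#'
#' @return An `mcanary_genome`.
#' @export
toy_genome <- function() {
  declare_genome(c(chr1 = 2e6, chr2 = 1e6))
}

#' Tile a genome into fixed-width bins
#'
#' @param genome An `mcanary_genome`.
#' @param bin_size Bin width in bp (default 100 kb).
#' @return data.table with columns chrom, start, end (0-based half-open),
#'   bin (global 1-based index).
#' @export
genome_bins <- function(genome, bin_size = 1e5) {
  stopifnot(bin_size >= 1)
  out <- data.table::rbindlist(lapply(names(genome), function(ch) {
    len <- genome[[ch]]
    starts <- seq(0L, len - 1L, by = as.integer(bin_size))
    data.table::data.table(
      chrom = ch, start = starts,
      end = pmin(starts + as.integer(bin_size), len))
  }))
  out[, bin := seq_len(.N)]
  out[]
}
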