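#' Strand-aware cfDNA fragment sets
#'
#' A `fragment_set` is a `data.table` with columns `chrom`, `start`, `end`
#' (0-based half-open) and `strand` (`+`/`-`), carrying the declared genome
#' as an attribute. All internal coordinates in this package are 0-based
#' half-open; 1-based inputs (SAM/BAM) are converted at the boundary.
#'
#' @param chrom,start,end,strand Vectors of equal length.
#' @param genome An `mcanary_genome` (see [declare_genome()]). Records on
#'   chromosomes absent from the genome are dropped with a message.
#' @return A `fragment_set`.
#' @export
fragment_set <- function(chrom, start, end, strand, genome) {
  dt <- data.table::data.table(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.character(strand))
  if (nrow(dt)) {
    if (any(is.na(dt$start)) || any(is.na(dt$end)))
      stop("fragment coordinates contain NA")
    if (any(dt$end <= dt$start))
      stop("fragment end must be > start (0-based half-open)")
    if (!all(dt$strand %in% c("+", "-")))
      stop("fragment strand must be '+' or '-'")
    unknown <- !(dt$chrom %in% names(genome))
    if (any(unknown)) {
      message(sum(unknown), " fragment(s) on chromosomes outside the ",
              "declared genome dropped")
      dt <- dt[!unknown]
    }
  }
  data.table::setattr(dt, "genome", genome)
  data.table::setattr(dt, "class", c("fragment_set", class(dt)))
  dt
}

#' @export
print.fragment_set <- function(x, ...) {
  cat("<fragment_set> ", nrow(x), " fragments on ",
      length(unique(x$chrom)), " chromosome(s)\n", sep = "")
  NextMethod()
}

fragments_genome <- function(fragments) {
  g <- attr(fragments, "genome")
  if (is.null(g)) stop("fragment_set has no genome attribute")
  g
}

#' Read aligned cfDNA fragments
#'
#' BED input is 0-based half-open and requires a strand column (BED6 by
#' default; `strand_col` declares other dialects). SAM/BAM input is
#' converted from 1-based closed to internal 0-based half-open coordinates;
#' unmapped records are skipped. Paired-end alignments yield one record per
#' read, not per template: the downstream 5'-end logic operates on reads.
#'
#' @param path Input file.
#' @param genome An `mcanary_genome`.
#' @param format `"bed"`, `"sam"` or `"bam"`; default guesses from the
#'   file extension.
#' @param strand_col Column holding the strand for BED input (default 6).
#' @return A [fragment_set()].
#' @export
read_fragments <- function(path, genome,
                           format = c("auto", "bed", "sam", "bam"),
                           strand_col = 6L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("fragment file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, bed = "bed", sam = "sam", bam = "bam",
                     stop("cannot guess fragment format from extension '",
                          ext, "'"))
  }
  if (format == "bed") read_fragments_bed(path, genome, strand_col)
  else read_fragments_sam(path, genome, format)
}

read_fragments_bed <- function(path, genome, strand_col) {
  dt <- suppressWarnings(
    data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                      colClasses = "character"))
  if (nrow(dt) == 0L) {
    warning("empty BED file: ", path)
    return(fragment_set(character(), integer(), integer(), character(),
                        genome))
  }
  if (ncol(dt) < strand_col)
    stop("BED file has ", ncol(dt), " columns; strand expected in column ",
         strand_col, " (strand is required by the 5'-end logic)")
  starts <- suppressWarnings(as.integer(dt[[2L]]))
  ends <- suppressWarnings(as.integer(dt[[3L]]))
  strands <- dt[[strand_col]]
  bad <- which(is.na(starts) | is.na(ends) | ends <= starts |
                 !(strands %in% c("+", "-")))
  if (length(bad))
    stop("unparseable BED record at line ", bad[1L], " of ", path,
         " (need integer start < end and strand +/-)")
  fragment_set(dt[[1L]], starts, ends, strands, genome)
}

read_fragments_sam <- function(path, genome, format) {
  bam <- if (format == "sam") {
    tmp <- tempfile(fileext = ".bam")
    Rsamtools::asBam(path, sub("\\.bam$", "", tmp),
                     overwrite = TRUE, indexDestination = FALSE)
  } else path
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  par <- Rsamtools::ScanBamParam(
    flag = flags, what = c("rname", "pos", "qwidth", "strand"))
  rec <- Rsamtools::scanBam(bam, param = par)[[1L]]
  keep <- !is.na(rec$pos) & !is.na(rec$qwidth)
  # SAM POS is 1-based; internal convention is 0-based half-open
  fragment_set(
    chrom = as.character(rec$rname)[keep],
    start = rec$pos[keep] - 1L,
    end = rec$pos[keep] - 1L + rec$qwidth[keep],
    strand = as.character(rec$strand)[keep],
    genome = genome)
}

#' Write fragments as BED6
#'
#' Round-trips bit-exactly with [read_fragments()] on BED input.
#'
#' @param fragments A [fragment_set()].
#' @param path Output path.
#' @export
write_fragments <- function(fragments, path) {
  out <- data.table::data.table(
    chrom = fragments$chrom, start = fragments$start, end = fragments$end,
    name = ".", score = 0L, strand = fragments$strand)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
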