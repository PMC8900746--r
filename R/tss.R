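#' 5'-end position of aligned reads
#'
#' Forward reads start at their leftmost coordinate; reverse reads have
#' their start adjusted by their length minus one base, i.e. the rightmost
#' covered base (`end - 1` in 0-based half-open coordinates).
#'
#' @param fragments A [fragment_set()] (or any data.frame with start, end,
#'   strand).
#' @return Integer vector of 0-based 5'-end positions.
#' @export
fragment_5prime_start <- function(fragments) {
  ifelse(fragments$strand == "+",
         fragments$start,
         fragments$end - 1L)
}

#' Nucleosome core windows from read 5' ends
#'
#' Each read's 5' end is extended to the canonical 167 bp cfDNA fragment
#' span and the central 61 bp (1-based offsets 53-113 within the
#' extension) are kept as the nucleosome-protected core. On the reverse
#' strand the extension runs leftward, so the window is the mirror image.
#' Windows that would extend past the chromosome boundaries are dropped and
#' counted in a message.
#'
#' @param start5p Integer vector of 0-based 5'-end positions.
#' @param strand Character vector of `+`/`-`.
#' @param chrom Chromosome of each read (recycled if length 1).
#' @param genome An `mcanary_genome` (used only for boundary checks; pass
#'   `NULL` to skip).
#' @param core_offset_start,core_offset_end 1-based inclusive offsets of
#'   the core within the extension (defaults 53 and 113, a 61 bp core).
#' @return data.table with chrom, start, end; every row has
#'   `end - start == core_offset_end - core_offset_start + 1`.
#' @export
nucleosome_core_window <- function(start5p, strand, chrom = NA_character_,
                                   genome = NULL,
                                   core_offset_start = 53L,
                                   core_offset_end = 113L) {
  fwd <- strand == "+"
  # 1-based offsets o_s..o_e inside the extension -> 0-based half-open
  start <- ifelse(fwd, start5p + core_offset_start - 1L,
                       start5p - core_offset_end + 1L)
  end <- ifelse(fwd, start5p + core_offset_end,
                     start5p - core_offset_start + 2L)
  out <- data.table::data.table(
    chrom = rep_len(chrom, length(start5p)),
    start = as.integer(start), end = as.integer(end))
  drop <- out$start < 0L
  if (!is.null(genome))
    drop <- drop | out$end > genome[out$chrom]
  if (any(drop)) {
    message(sum(drop), " core window(s) past chromosome boundaries dropped")
    out <- out[!drop]
  }
  out[]
}

#' Per-base depth of core windows over a region
#'
#' `depth[p]` is the number of windows covering position `p`. Implemented
#' as an interval sweep via [IRanges::coverage()]; the test-suite checks it
#' against a brute-force per-base oracle.
#'
#' @param windows data.table of windows (chrom, start, end) on a single
#'   chromosome.
#' @param region_start,region_end 0-based half-open region to report.
#' @return Integer vector of length `region_end - region_start`.
#' @export
site_depth <- function(windows, region_start, region_end) {
  stopifnot(region_end > region_start)
  if (nrow(windows) && length(unique(windows$chrom)) > 1L)
    stop("site_depth expects windows on a single chromosome")
  if (!nrow(windows)) return(integer(region_end - region_start))
  ir <- IRanges::IRanges(start = windows$start + 1L, end = windows$end)
  cov <- IRanges::coverage(ir, width = max(region_end, max(windows$end)))
  as.integer(S4Vectors::window(cov, start = region_start + 1L,
                               end = region_end))
}

# Whole-genome coverage of core windows as an RleList keyed by chromosome.
windows_coverage <- function(windows, genome) {
  out <- lapply(names(genome), function(ch) {
    w <- windows[windows$chrom == ch, ]
    if (!nrow(w)) return(S4Vectors::Rle(0L, genome[[ch]]))
    IRanges::coverage(IRanges::IRanges(start = w$start + 1L, end = w$end),
                      width = genome[[ch]])
  })
  names(out) <- names(genome)
  out
}

#' Per-100kb fragment counts and copy ratios
#'
#' Counts read 5' ends in fixed-width bins and expresses each bin as a
#' ratio to the genome-wide median over non-empty autosomal bins
#' (a simplified, segmentation-free stand-in for an HMM copy-number
#' caller). Ratios are clamped to `clamp` so the downstream depth
#' normalization always has a safe divisor.
#'
#' @param fragments A [fragment_set()].
#' @param bin_size Bin width (default 100 kb).
#' @param clamp Two-element ratio clamp (default `c(0.1, 10)`).
#' @return data.table of class `bin_copy_ratio` with chrom, start, end,
#'   bin, count, ratio, log2_ratio.
#' @export
bin_copy_ratio <- function(fragments, bin_size = 1e5, clamp = c(0.1, 10)) {
  if (nrow(fragments) == 0L) stop("no fragments: all bins empty")
  genome <- fragments_genome(fragments)
  bins <- genome_bins(genome, bin_size)
  p5 <- fragment_5prime_start(fragments)
  counts <- integer(nrow(bins))
  for (ch in names(genome)) {
    sel <- fragments$chrom == ch
    if (!any(sel)) next
    idx <- which(bins$chrom == ch)
    b <- findInterval(p5[sel], bins$start[idx])
    b <- b[b >= 1L & b <= length(idx)]
    tab <- tabulate(b, nbins = length(idx))
    counts[idx] <- counts[idx] + tab
  }
  bins[, count := counts]
  ref <- bins[count > 0L & chrom %in% autosome_names(), count]
  if (!length(ref)) stop("all autosomal bins empty")
  med <- stats::median(ref)
  bins[, ratio := pmin(pmax(count / med, clamp[1L]), clamp[2L])]
  bins[, log2_ratio := log2(ratio)]
  data.table::setattr(bins, "bin_size", bin_size)
  data.table::setattr(bins, "class",
                      c("bin_copy_ratio", class(data.table::data.table())))
  bins[]
}

#' Normalize per-base depth by the local copy ratio
#'
#' Divides depth by the *linear* copy ratio of the 100 kb bin containing
#' each position (the clamp in [bin_copy_ratio()] guarantees a safe
#' divisor). This removes copy-number bias from the TSS coverage signal so
#' that nucleosome occupancy, not tumor CNV, drives the downstream
#' correlation.
#'
#' @param depth Numeric per-base depth over
#'   `[region_start, region_start + length(depth))` on `chrom`.
#' @param bins A [bin_copy_ratio()].
#' @param chrom Chromosome name.
#' @param region_start 0-based start of the depth vector (default 0).
#' @return Numeric vector of normalized depth.
#' @export
cnv_normalize_depth <- function(depth, bins, chrom, region_start = 0L) {
  pos <- region_start + seq_along(depth) - 1L
  b <- bins[bins$chrom == chrom, ]
  if (!nrow(b)) stop("no bins for chromosome ", chrom)
  idx <- findInterval(pos, b$start)
  if (any(idx < 1L) || any(pos >= b$end[nrow(b)] + 0L & idx > nrow(b)))
    stop("positions outside binned chromosome ", chrom)
  depth / b$ratio[idx]
}

# RleList version used by the whole-genome pipeline: divide each
# chromosome's coverage by its per-bin ratio expressed as an Rle.
normalize_coverage <- function(cov, bins) {
  out <- lapply(names(cov), function(ch) {
    b <- bins[bins$chrom == ch, ]
    if (!nrow(b)) return(cov[[ch]])
    ratio_rle <- S4Vectors::Rle(b$ratio, b$end - b$start)
    cov[[ch]] / ratio_rle
  })
  names(out) <- names(cov)
  out
}

#' Per-gene RDPKM around transcription start sites
#'
#' For each transcript, depth is accumulated over the TSS +/- `flank`
#' window and normalized as read depth per kilobase per million mapped
#' reads: `RDPKM = sum(depth) / (window_kb * total_mapped / 1e6)`. Genes
#' with several transcripts get the mean RDPKM over their transcripts.
#' Transcript windows extending past a chromosome are skipped and counted.
#'
#' @param normalized_depth Named list of per-chromosome depth Rle (from the
#'   internal coverage pipeline) or plain numeric vectors starting at
#'   position 0.
#' @param tss TSS annotation data.table (see [read_tss_table()]).
#' @param total_mapped Total mapped read count used for the per-million
#'   scaling.
#' @param flank Flank on each side of the TSS in bp (default 1,000, i.e. a
#'   2 kb window).
#' @return List of class `rdpkm_profile`: `rdpkm` (named per-gene vector),
#'   `transcript_rdpkm`, `total_mapped`, `flank`.
#' @export
gene_rdpkm <- function(normalized_depth, tss, total_mapped, flank = 1000L) {
  stopifnot(total_mapped > 0)
  tss <- data.table::as.data.table(tss)
  window_kb <- (2 * flank) / 1000
  per_million <- total_mapped / 1e6
  sums <- rep(NA_real_, nrow(tss))
  skipped <- 0L
  for (ch in unique(tss$chrom)) {
    dep <- normalized_depth[[ch]]
    if (is.null(dep)) { skipped <- skipped + sum(tss$chrom == ch); next }
    len <- length(dep)
    idx <- which(tss$chrom == ch)
    ws <- tss$tss[idx] - flank
    we <- tss$tss[idx] + flank           # 0-based half-open window
    ok <- ws >= 0L & we <= len
    skipped <- skipped + sum(!ok)
    if (!any(ok)) next
    if (is(dep, "Rle")) {
      v <- IRanges::Views(dep, start = ws[ok] + 1L, end = we[ok])
      sums[idx[ok]] <- IRanges::viewSums(v)
    } else {
      sums[idx[ok]] <- vapply(which(ok), function(j)
        sum(dep[(ws[j] + 1L):we[j]]), numeric(1))
    }
  }
  if (skipped) message(skipped, " transcript window(s) off-chromosome skipped")
  tdt <- data.table::data.table(
    gene_id = tss$gene_id, transcript_id = tss$transcript_id,
    rdpkm = sums / (window_kb * per_million))
  tdt <- tdt[!is.na(rdpkm)]
  gdt <- tdt[, .(rdpkm = mean(rdpkm)), by = gene_id]
  structure(list(
    rdpkm = setNames(gdt$rdpkm, gdt$gene_id),
    transcript_rdpkm = tdt[],
    total_mapped = total_mapped,
    flank = flank),
    class = "rdpkm_profile")
}

#' Full TSS coverage pipeline: fragments to RDPKM profile
#'
#' Chains 5'-end adjustment, nucleosome core windows, genome-wide
#' coverage, 100 kb copy-ratio normalization and per-gene RDPKM.
#'
#' @param fragments A [fragment_set()].
#' @param tss TSS annotation table.
#' @param cfg A [pipeline_config()].
#' @return An [gene_rdpkm()] profile.
#' @export
tss_coverage_profile <- function(fragments, tss, cfg = pipeline_config()) {
  genome <- fragments_genome(fragments)
  p5 <- fragment_5prime_start(fragments)
  win <- nucleosome_core_window(
    p5, fragments$strand, fragments$chrom, genome,
    core_offset_start = cfg$core_offset_start,
    core_offset_end = cfg$core_offset_end)
  cov <- windows_coverage(win, genome)
  bins <- bin_copy_ratio(fragments, bin_size = cfg$bin_size,
                         clamp = cfg$ratio_clamp)
  norm <- normalize_coverage(cov, bins)
  gene_rdpkm(norm, tss, total_mapped = nrow(fragments),
             flank = cfg$tss_flank)
}

#' @export
print.rdpkm_profile <- function(x, ...) {
  cat("<rdpkm_profile> ", length(x$rdpkm), " genes, total_mapped = ",
      x$total_mapped, ", flank = ", x$flank, " bp\n", sep = "")
  invisible(x)
}
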