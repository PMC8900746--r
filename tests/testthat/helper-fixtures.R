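# Shared fixtures and independent oracles. Oracles are deliberately naive
# (brute force / two-pass / O(n^2)) and never call the code paths they check.

# named z-score vector over chr1..chr22, chrX (+ optional chrY), zeros
# except for the overrides
make_z <- function(..., chrY = NULL) {
  over <- list(...)
  chroms <- setdiff(chromosome_names(), "chrY")
  z <- setNames(rep(0, length(chroms)), chroms)
  z[names(over)] <- unlist(over)
  if (!is.null(chrY)) z <- c(z, chrY = chrY)
  chrom_zscores(z)
}

tiny_genome <- function() declare_genome(c(chr1 = 10000, chr2 = 5000))

# brute-force MTOP5Zscores: sort |z| over the 22 candidates, average top 5
oracle_mtop5 <- function(z, exclude = c("chr19", "chrY")) {
  cand <- setdiff(intersect(chromosome_names(), names(z)), exclude)
  mean(sort(abs(z[cand]), decreasing = TRUE)[1:5])
}

# O(n * L) per-base depth oracle
oracle_depth <- function(windows, region_start, region_end) {
  depth <- integer(region_end - region_start)
  for (i in seq_len(nrow(windows))) {
    s <- max(windows$start[i], region_start)
    e <- min(windows$end[i], region_end)
    if (e > s) {
      idx <- (s - region_start + 1L):(e - region_start)
      depth[idx] <- depth[idx] + 1L
    }
  }
  depth
}

# O(n^2) pairwise Mann-Whitney AUC oracle, ties counted 1/2
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# textbook two-pass Pearson correlation
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# random z-score vector generator for property tests
random_z <- function() {
  chroms <- setdiff(chromosome_names(), "chrY")
  chrom_zscores(setNames(rnorm(length(chroms), 0, 5), chroms))
}

write_temp_bed <- function(lines) {
  path <- withr::local_tempfile(fileext = ".bed",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# minimal valid SAM with real sequences so query widths are defined
write_temp_sam <- function() {
  path <- withr::local_tempfile(fileext = ".sam",
                                .local_envir = parent.frame())
  seq100 <- strrep("A", 100)
  qual100 <- strrep("I", 100)
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:10000",
    paste("r1", 0, "chr1", 1001, 60, "100M", "*", 0, 0, seq100, qual100,
          sep = "\t"),
    paste("r2", 16, "chr1", 2001, 60, "100M", "*", 0, 0, seq100, qual100,
          sep = "\t")), path)
  path
}
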