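#' Filter genes before the NPCC correlation
#'
#' Keeps genes that (a) are present in the profile and in every expression
#' reference, (b) have RDPKM >= 100 (low-coverage genes removed), and (c)
#' have log2(mean FPKM) >= 0.1 in every reference (near-silent genes
#' removed). Both thresholds follow the published strict-`<` elimination
#' rules, so the boundary values are retained.
#'
#' @param profile An `rdpkm_profile`.
#' @param refs Named list of `expression_reference`.
#' @param rdpkm_min RDPKM elimination threshold (default 100).
#' @param log2_fpkm_min log2(mean FPKM) elimination threshold (default 0.1).
#' @return Character vector of retained gene ids.
#' @export
filter_genes <- function(profile, refs, rdpkm_min = 100,
                         log2_fpkm_min = 0.1) {
  genes <- names(profile$rdpkm)
  for (r in refs) genes <- intersect(genes, names(r))
  dropped <- length(names(profile$rdpkm)) - length(genes)
  if (dropped) message(dropped, " gene(s) absent from a reference dropped")
  keep <- profile$rdpkm[genes] >= rdpkm_min
  for (r in refs)
    keep <- keep & log2(as.numeric(r[genes])) >= log2_fpkm_min
  retained <- genes[keep]
  if (!length(retained))
    stop("no genes pass the RDPKM/FPKM filters; correlation undefined")
  retained
}

#' Normalized Pearson correlation coefficients against tissue references
#'
#' For each reference cancer type i, `R_i` is the Pearson correlation
#' between the sample's per-gene RDPKM and the type's mean FPKM over the
#' retained genes (TSS coverage is anticorrelated with expression in the
#' contributing tissue, so the matching type tends to the most negative
#' `R_i`). The normalized coefficient is `NPCC_i = R_i / sum_j R_j`, which
#' sums to 1 whenever defined.
#'
#' @param profile An `rdpkm_profile`.
#' @param refs Named list of `expression_reference` (typically BRCA, DLBC,
#'   LIHC).
#' @param retained Retained gene ids; default recomputed via
#'   [filter_genes()].
#' @param rdpkm_min,log2_fpkm_min Passed to [filter_genes()] when
#'   `retained` is `NULL`.
#' @return List of class `npcc_vector`: `r_raw`, `npcc` (both named by
#'   cancer type), `n_genes_used`.
#' @export
compute_npcc <- function(profile, refs, retained = NULL,
                         rdpkm_min = 100, log2_fpkm_min = 0.1) {
  if (is.null(retained))
    retained <- filter_genes(profile, refs, rdpkm_min, log2_fpkm_min)
  if (length(retained) < 3L)
    stop("need >= 3 retained genes for a correlation, got ",
         length(retained))
  x <- profile$rdpkm[retained]
  if (stats::sd(x) == 0) stop("RDPKM constant over retained genes")
  r_raw <- vapply(refs, function(r) {
    y <- as.numeric(r[retained])
    if (stats::sd(y) == 0)
      stop("reference '", attr(r, "cancer_type"),
           "' constant over retained genes")
    stats::cor(x, y)
  }, numeric(1))
  s <- sum(r_raw)
  if (abs(s) < 1e-8)
    stop("NPCC undefined (coefficients cancel: sum of correlations ~ 0)")
  structure(list(r_raw = r_raw, npcc = r_raw / s,
                 n_genes_used = length(retained)),
            class = "npcc_vector")
}

#' @export
print.npcc_vector <- function(x, ...) {
  cat("<npcc_vector> over", x$n_genes_used, "genes\n")
  print(round(rbind(r_raw = x$r_raw, npcc = x$npcc), 4))
  invisible(x)
}
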