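#' Cohort simulation specification
#'
#' The stated world of the simulator. Per-class per-chromosome
#' amplification/deletion probabilities default to the published
#' frequencies where they are printed and to documented placeholders where
#' only a floor is printed:
#' \itemize{
#'   \item liver: amplifications chr20 69.2%, chr1/chr2/chr6/chr7 61.5%;
#'     deletions chr4 92.3%, chr18 69.2%, chr13/chr16 61.5%, chr15 53.8%.
#'   \item breast: top-5 amplified chr1, chr8, chr20, chr7, chr21 and
#'     deleted chr14, chr22, chr4, chr5, chr10, all printed only as
#'     ">50%": placeholder 0.55.
#'   \item lymphoma: amplified chr2, chr19, chr12, chr5, chr9 and deleted
#'     chr4, chr13, chrX, chr6, chr10, printed as ">44.4%":
#'     placeholder 0.50.
#'   \item gastric: amplified chr7, chr8, chr19, chr1, chr20 and deleted
#'     chr4, chrX, chr5, chr15, chr21, printed as ">42.9%":
#'     placeholder 0.48.
#'   \item non-cancer: only the chr19 technical artifact (deletion
#'     53.92%, amplification 21.89%) plus baseline noise.
#' }
#' Affected chromosomes draw |z| from a shifted gamma with minimum
#' `effect_min` (3.2 > the MCA threshold), unaffected chromosomes draw
#' `N(0, baseline_sd)`. Plasma tumor markers are log-normal; the
#' non-cancer location and the cancer "driver" shift are calibrated in
#' closed form to the published any-marker operating point (sensitivity
#' 66.07%, specificity 93.13%) before any data are drawn. Class NPCC
#' vectors put the most negative raw correlation on the matching
#' reference tissue.
#'
#' @param n Named subject counts per class; defaults mirror the published
#'   classifier class sizes plus controls:
#'   breast 15, gastric 7, liver 12, lymphoma 8, non_cancer 400.
#' @param amp_prob,del_prob Optional class x chromosome probability
#'   overrides (matrices with chromosome columns).
#' @param effect_min,effect_shape,effect_scale Shifted-gamma |z| magnitude
#'   for affected chromosomes (default min 3.2, shape 2, scale 1.5).
#' @param baseline_sd Baseline z-score noise SD (default 1.5: the
#'   non-cancer arm of the cohort is itself MCA-enriched, so its residual
#'   chromosome noise is wider than a pure euploid panel's unit SD).
#' @param ptm_sdlog Log-normal scale of each marker (default 0.5).
#' @param ptm_driver_shift Log-location shift of class driver markers;
#'   `NULL` (default) calibrates it via [calibrate_ptm_shift()].
#' @param ptm_base_shift Mild log-location shift of non-driver markers in
#'   cancer (default 0.3).
#' @param seed Integer seed recorded in the spec.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n = c(breast = 15, gastric = 7, liver = 12,
                              lymphoma = 8, non_cancer = 400),
                        amp_prob = NULL, del_prob = NULL,
                        effect_min = 3.2, effect_shape = 2,
                        effect_scale = 1.5, baseline_sd = 1.5,
                        ptm_sdlog = 0.5, ptm_driver_shift = NULL,
                        ptm_base_shift = 0.3, seed = 1L) {
  classes <- c("breast", "gastric", "liver", "lymphoma", "non_cancer")
  if (!all(names(n) %in% classes)) stop("unknown class in n")
  full_n <- setNames(rep(0L, length(classes)), classes)
  full_n[names(n)] <- as.integer(n)

  mk <- function() matrix(0, length(classes), 24,
                          dimnames = list(classes, chromosome_names()))
  ap <- mk(); dp <- mk()
  ap["liver", c("chr20", "chr1", "chr2", "chr6", "chr7")] <-
    c(0.692, 0.615, 0.615, 0.615, 0.615)
  dp["liver", c("chr4", "chr18", "chr13", "chr16", "chr15")] <-
    c(0.923, 0.692, 0.615, 0.615, 0.538)
  ap["breast", c("chr1", "chr8", "chr20", "chr7", "chr21")] <- 0.55
  dp["breast", c("chr14", "chr22", "chr4", "chr5", "chr10")] <- 0.55
  ap["lymphoma", c("chr2", "chr19", "chr12", "chr5", "chr9")] <- 0.50
  dp["lymphoma", c("chr4", "chr13", "chrX", "chr6", "chr10")] <- 0.50
  ap["gastric", c("chr7", "chr8", "chr19", "chr1", "chr20")] <- 0.48
  dp["gastric", c("chr4", "chrX", "chr5", "chr15", "chr21")] <- 0.48
  ap["non_cancer", "chr19"] <- 0.2189
  dp["non_cancer", "chr19"] <- 0.5392
  if (!is.null(amp_prob)) ap[rownames(amp_prob), colnames(amp_prob)] <- amp_prob
  if (!is.null(del_prob)) dp[rownames(del_prob), colnames(del_prob)] <- del_prob
  if (any(ap + dp > 1)) stop("amp_prob + del_prob must be <= 1")

  cutoffs <- default_ptm_cutoffs()
  # non-cancer log-location pinned to the published 93.13% specificity of
  # the any-marker rule: equal per-marker tail q with 1-(1-q)^7 = 1-0.9313
  spec_target <- 0.9313
  q <- 1 - spec_target^(1 / length(cutoffs))
  ptm_meanlog <- log(cutoffs) - stats::qnorm(1 - q) * ptm_sdlog
  drivers <- list(
    breast = c("CA15-3", "CA125", "CEA"),
    liver = "AFP",
    gastric = c("CA72-4", "CEA", "CA19-9"),
    lymphoma = "CYFRA21-1")
  if (is.null(ptm_driver_shift))
    ptm_driver_shift <- calibrate_ptm_shift(
      cutoffs, ptm_meanlog, ptm_sdlog, drivers,
      base_shift = ptm_base_shift,
      class_weights = c(breast = 15, gastric = 7, liver = 12,
                        lymphoma = 8) / 42,
      target_sensitivity = 0.6607)

  # class-conditional NPCC raw-correlation model: the matching reference
  # tissue is the most negative; gastric / non-cancer have no match
  npcc_match <- c(breast = "BRCA", lymphoma = "DLBC", liver = "LIHC")

  structure(list(
    classes = classes, n = full_n, amp_prob = ap, del_prob = dp,
    effect_min = effect_min, effect_shape = effect_shape,
    effect_scale = effect_scale, baseline_sd = baseline_sd,
    ptm_cutoffs = cutoffs, ptm_meanlog = ptm_meanlog,
    ptm_sdlog = ptm_sdlog, ptm_drivers = drivers,
    ptm_driver_shift = ptm_driver_shift, ptm_base_shift = ptm_base_shift,
    npcc_match = npcc_match, npcc_r_match = -0.5, npcc_r_other = -0.25,
    npcc_r_sd = 0.06, p_male_fetus = 0.5, seed = as.integer(seed)),
    class = "cohort_spec")
}

#' Closed-form calibration of the cancer PTM driver shift
#'
#' Under the log-normal marker model, the probability that marker m of a
#' cancer subject exceeds its cutoff is
#' `1 - pnorm((log cutoff - meanlog_m - shift_m) / sdlog)`, and a class's
#' any-marker sensitivity is one minus the product of the per-marker
#' non-exceedance probabilities. The driver shift solves (via uniroot) for
#' the class-weighted sensitivity equal to the target. Purely analytic:
#' no simulated data are consumed.
#'
#' @param cutoffs,meanlog,sdlog Marker model parameters.
#' @param drivers Named list: class -> driver marker names.
#' @param base_shift Non-driver cancer shift.
#' @param class_weights Named class weights summing to 1.
#' @param target_sensitivity Target any-marker sensitivity.
#' @return The driver shift (scalar).
#' @export
calibrate_ptm_shift <- function(cutoffs, meanlog, sdlog, drivers,
                                base_shift, class_weights,
                                target_sensitivity) {
  class_sens <- function(shift) {
    vapply(names(class_weights), function(cl) {
      shifts <- setNames(rep(base_shift, length(cutoffs)), names(cutoffs))
      shifts[drivers[[cl]]] <- shift
      p_exceed <- 1 - stats::pnorm(
        (log(cutoffs) - meanlog - shifts) / sdlog)
      1 - prod(1 - p_exceed)
    }, numeric(1))
  }
  f <- function(shift)
    sum(class_weights * class_sens(shift)) - target_sensitivity
  stats::uniroot(f, c(0, 8), tol = 1e-10)$root
}

#' Simulate one subject's chromosome z-scores
#'
#' Each chromosome is independently amplified (z = +|effect|), deleted
#' (z = -|effect|) or neutral (`N(0, baseline_sd)`) with the class's
#' probabilities; |effect| is `effect_min + Gamma(shape, scale)`. chrY is
#' present (baseline noise only) with probability `p_male_fetus`.
#' Uses R's global RNG: seed the caller for reproducibility.
#'
#' @param class Class name in the spec.
#' @param spec A [cohort_spec()].
#' @return A [chrom_zscores()].
#' @export
simulate_zscores <- function(class, spec = cohort_spec()) {
  if (!class %in% spec$classes) stop("unknown class: ", class)
  male <- stats::runif(1) < spec$p_male_fetus
  chroms <- if (male) chromosome_names() else
    setdiff(chromosome_names(), "chrY")
  pa <- spec$amp_prob[class, chroms]
  pd <- spec$del_prob[class, chroms]
  u <- stats::runif(length(chroms))
  state <- ifelse(u < pa, "amp", ifelse(u < pa + pd, "del", "none"))
  mag <- spec$effect_min +
    stats::rgamma(length(chroms), shape = spec$effect_shape,
                  scale = spec$effect_scale)
  z <- stats::rnorm(length(chroms), 0, spec$baseline_sd)
  z[state == "amp"] <- mag[state == "amp"]
  z[state == "del"] <- -mag[state == "del"]
  chrom_zscores(setNames(z, chroms))
}

#' Simulate one subject's plasma tumor marker panel
#'
#' @inheritParams simulate_zscores
#' @return A [ptm_panel()].
#' @export
simulate_ptm <- function(class, spec = cohort_spec()) {
  if (!class %in% spec$classes) stop("unknown class: ", class)
  shifts <- setNames(rep(0, length(spec$ptm_cutoffs)),
                     names(spec$ptm_cutoffs))
  if (class != "non_cancer") {
    shifts[] <- spec$ptm_base_shift
    shifts[spec$ptm_drivers[[class]]] <- spec$ptm_driver_shift
  }
  conc <- stats::rlnorm(length(shifts),
                        meanlog = spec$ptm_meanlog + shifts,
                        sdlog = spec$ptm_sdlog)
  ptm_panel(setNames(conc, names(spec$ptm_cutoffs)))
}

#' Simulate one subject's NPCC vector
#'
#' Raw correlations are negative (TSS coverage anticorrelates with
#' expression); the class's matching reference tissue gets the most
#' negative draw, classes without a matching reference (gastric,
#' non-cancer) draw a flat profile. Normalization to `r / sum(r)` follows.
#'
#' @inheritParams simulate_zscores
#' @return An `npcc_vector`.
#' @export
simulate_npcc <- function(class, spec = cohort_spec()) {
  types <- c("BRCA", "DLBC", "LIHC")
  mu <- setNames(rep(spec$npcc_r_other, 3), types)
  match_type <- spec$npcc_match[class]
  if (!is.na(match_type)) mu[match_type] <- spec$npcc_r_match
  r <- setNames(stats::rnorm(3, mu, spec$npcc_r_sd), types)
  structure(list(r_raw = r, npcc = r / sum(r),
                 n_genes_used = NA_integer_),
            class = "npcc_vector")
}

#' Simulate a labeled cohort
#'
#' Draws z-scores, PTM panels and NPCC vectors for every subject in the
#' spec, in a deterministic class-then-index order under `spec$seed`
#' (byte-identical output for equal seeds).
#'
#' @param spec A [cohort_spec()].
#' @return List of class `cohort`: `subjects` (list of records with id,
#'   label, z, ptm, npcc), `spec`.
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  set.seed(spec$seed)
  subjects <- list()
  for (cl in spec$classes) {
    for (i in seq_len(spec$n[[cl]])) {
      id <- sprintf("%s_%03d", cl, i)
      subjects[[id]] <- list(
        subject_id = id, label = cl,
        z = simulate_zscores(cl, spec),
        ptm = simulate_ptm(cl, spec),
        npcc = simulate_npcc(cl, spec))
    }
  }
  structure(list(subjects = subjects, spec = spec), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  labs <- vapply(x$subjects, `[[`, character(1), "label")
  cat("<cohort> n =", length(labs), "\n")
  print(table(labs))
  invisible(x)
}

#' Extract cohort pieces as analysis-ready tables
#'
#' @param cohort A [simulate_cohort()] result.
#' @return `cohort_labels`: named character vector of labels.
#' @export
cohort_labels <- function(cohort)
  vapply(cohort$subjects, `[[`, character(1), "label")

#' @rdname cohort_labels
#' @export
cohort_zscores <- function(cohort)
  lapply(cohort$subjects, `[[`, "z")

#' @rdname cohort_labels
#' @param cancer_only Keep only the four cancer classes (the classifier's
#'   domain).
#' @export
cohort_feature_matrix <- function(cohort, cancer_only = TRUE) {
  subs <- cohort$subjects
  if (cancer_only)
    subs <- subs[vapply(subs, `[[`, character(1), "label") != "non_cancer"]
  mat <- t(vapply(subs, function(s)
    assemble_features(s$npcc, s$z, s$ptm),
    numeric(length(classifier_feature_names()))))
  rownames(mat) <- names(subs)
  list(features = mat,
       labels = vapply(subs, `[[`, character(1), "label"))
}

#' Write a cohort to disk as plain-text tables
#'
#' Writes `zscores.tsv`, `ptm.csv` and `labels.tsv` under `dir`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_zscore_table(cohort_zscores(cohort), file.path(dir, "zscores.tsv"))
  markers <- names(default_ptm_cutoffs())
  ptm <- data.table::rbindlist(lapply(cohort$subjects, function(s)
    c(list(subject_id = s$subject_id), as.list(as.numeric(s$ptm)))))
  data.table::setnames(ptm, c("subject_id", markers))
  data.table::fwrite(ptm, file.path(dir, "ptm.csv"))
  labs <- data.table::data.table(
    subject_id = names(cohort$subjects),
    label = cohort_labels(cohort))
  data.table::fwrite(labs, file.path(dir, "labels.tsv"), sep = "\t")
  invisible(dir)
}

#' Simulate per-cancer-type expression references
#'
#' Log-normal FPKM with a shared gene baseline, per-type noise, and a
#' disjoint high-expression gene block per type, so the references are
#' correlated (shared transcriptome) but distinguishable (pairwise
#' correlation of log FPKM < 0.9) and tissue recovery is possible.
#'
#' @param n_genes Number of genes (>= 10).
#' @param types Cancer types (default BRCA, DLBC, LIHC).
#' @param seed Optional integer seed.
#' @param high_shift Log-scale elevation of a type's own block
#'   (default 2.5).
#' @param noise_sd Per-type log-scale noise (default 0.6).
#' @return Named list of `expression_reference`, with attribute
#'   `high_block` (list of each type's elevated gene ids).
#' @export
simulate_expression_reference <- function(n_genes,
                                          types = c("BRCA", "DLBC", "LIHC"),
                                          seed = NULL, high_shift = 2.5,
                                          noise_sd = 0.6) {
  if (n_genes < 10L) stop("need >= 10 genes")
  if (!is.null(seed)) set.seed(seed)
  genes <- sprintf("G%05d", seq_len(n_genes))
  baseline <- stats::rnorm(n_genes, mean = log(5), sd = 1)
  block_size <- n_genes %/% (2L * length(types))
  blocks <- lapply(seq_along(types), function(k)
    genes[((k - 1L) * block_size + 1L):(k * block_size)])
  names(blocks) <- types
  refs <- lapply(types, function(tp) {
    lf <- baseline + stats::rnorm(n_genes, 0, noise_sd)
    lf[genes %in% blocks[[tp]]] <- lf[genes %in% blocks[[tp]]] + high_shift
    expression_reference(setNames(exp(lf), genes), tp)
  })
  names(refs) <- types
  attr(refs, "high_block") <- blocks
  refs
}

#' Simulate a TSS annotation over a genome
#'
#' Genes are spaced evenly (with jitter) so TSS +/- flank windows are
#' disjoint and away from chromosome edges; a fraction of genes get a
#' second transcript at the same TSS.
#'
#' @param genome An `mcanary_genome`.
#' @param n_genes Number of genes.
#' @param flank Window flank the spacing must respect (default 1,000).
#' @param seed Optional integer seed.
#' @return TSS data.table (gene_id, transcript_id, chrom, tss, strand).
#' @export
simulate_tss <- function(genome, n_genes, flank = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  total <- sum(as.numeric(genome))
  per_chrom <- setNames(pmax(1L, round(n_genes * as.numeric(genome) / total)),
                        names(genome))
  spacing_ok <- all(genome / (per_chrom + 1L) > 2.4 * flank)
  if (!spacing_ok) stop("too many genes for disjoint TSS windows")
  rows <- lapply(names(genome), function(ch) {
    k <- per_chrom[[ch]]
    step <- (genome[[ch]] - 4L * flank) / k
    tss <- as.integer(2L * flank + step * (seq_len(k) - 0.5) +
                        stats::runif(k, -0.1 * step, 0.1 * step))
    data.table::data.table(chrom = ch, tss = tss,
                           strand = sample(c("+", "-"), k, replace = TRUE))
  })
  dt <- data.table::rbindlist(rows)
  dt[, gene_id := sprintf("G%05d", seq_len(.N))]
  dt[, transcript_id := paste0(gene_id, ".1")]
  # ~20% of genes carry a second transcript at the same TSS
  second <- dt[stats::runif(.N) < 0.2]
  if (nrow(second)) {
    second[, transcript_id := paste0(gene_id, ".2")]
    dt <- rbind(dt, second)
  }
  validate_tss_table(dt[, .(gene_id, transcript_id, chrom, tss, strand)])
}

#' Fragment-simulation specification
#'
#' @param tissue Contributing tissue: a cancer type with an expression
#'   reference (`"BRCA"`, `"DLBC"`, `"LIHC"`) or `"none"` for a flat
#'   (non-tumor) sample.
#' @param tss TSS annotation table (e.g. [simulate_tss()]).
#' @param refs Expression references
#'   (e.g. [simulate_expression_reference()]).
#' @param genome An `mcanary_genome` (default [toy_genome()]).
#' @param n_fragments Fragments to draw before TSS thinning
#'   (default 150,000: ~3x nucleosome-core coverage of the toy genome,
#'   comparable to a shallow-WGS NIPT library scaled to genome size).
#' @param depletion Fraction of TSS-window coverage removed for the most
#'   expressed gene, scaled down by expression rank (default 0.7).
#' @param cnv_segments Optional data.table (chrom, start, end, ratio) of
#'   copy-altered segments.
#' @param frag_mean,frag_sd Fragment length distribution (default 167/10,
#'   the cfDNA mononucleosome peak).
#' @param seed Integer seed.
#' @return List of class `fragment_sim_spec`.
#' @export
fragment_sim_spec <- function(tissue, tss, refs, genome = toy_genome(),
                              n_fragments = 150000L, depletion = 0.7,
                              cnv_segments = NULL, frag_mean = 167,
                              frag_sd = 10, seed = 1L) {
  stopifnot(depletion >= 0, depletion <= 1, n_fragments >= 1)
  if (!identical(tissue, "none") && !tissue %in% names(refs))
    stop("tissue must be 'none' or one of: ",
         paste(names(refs), collapse = ", "))
  if (!is.null(cnv_segments)) {
    cnv_segments <- data.table::as.data.table(cnv_segments)
    stopifnot(all(cnv_segments$ratio > 0))
  }
  structure(list(tissue = tissue, tss = tss, refs = refs, genome = genome,
                 n_fragments = as.integer(n_fragments),
                 depletion = depletion, cnv_segments = cnv_segments,
                 frag_mean = frag_mean, frag_sd = frag_sd,
                 seed = as.integer(seed)),
            class = "fragment_sim_spec")
}

#' Simulate a cfDNA fragment set with nucleosome-footprint TSS signal
#'
#' Fragments are drawn from a genome-wide background whose local rate is
#' scaled by the copy ratio inside CNV segments. Fragments whose 5' end
#' falls in a TSS +/- flank window are thinned with probability
#' `depletion * expression_rank(gene)` in the chosen tissue, producing the
#' negative coverage-expression correlation that the NPCC layer detects.
#'
#' @param spec A [fragment_sim_spec()].
#' @param flank TSS window flank used for thinning (default 1,000).
#' @return A [fragment_set()] with attribute `truth` (tissue, depletion,
#'   seed).
#' @export
simulate_fragments <- function(spec, flank = 1000L) {
  set.seed(spec$seed)
  genome <- spec$genome
  # piecewise-constant rate regions: genome split at CNV breakpoints
  regions <- data.table::rbindlist(lapply(names(genome), function(ch) {
    bp <- c(0L, genome[[ch]])
    seg <- spec$cnv_segments
    if (!is.null(seg)) {
      s <- seg[seg$chrom == ch, ]
      bp <- sort(unique(c(bp, s$start, s$end)))
    }
    out <- data.table::data.table(chrom = ch, start = bp[-length(bp)],
                                  end = bp[-1L], ratio = 1)
    if (!is.null(seg)) {
      s <- seg[seg$chrom == ch, ]
      for (j in seq_len(nrow(s)))
        out[start >= s$start[j] & end <= s$end[j], ratio := s$ratio[j]]
    }
    out
  }))
  w <- (regions$end - regions$start) * regions$ratio
  reg <- sample.int(nrow(regions), spec$n_fragments, replace = TRUE,
                    prob = w / sum(w))
  left <- regions$start[reg] + floor(stats::runif(spec$n_fragments) *
                                       (regions$end - regions$start)[reg])
  len <- pmax(80L, as.integer(round(
    stats::rnorm(spec$n_fragments, spec$frag_mean, spec$frag_sd))))
  strand <- ifelse(stats::runif(spec$n_fragments) < 0.5, "+", "-")
  chrom <- regions$chrom[reg]
  start <- as.integer(left)
  end <- as.integer(left + len)
  # clip to chromosome
  lenv <- genome[chrom]
  keep <- end <= lenv & start >= 0L
  chrom <- chrom[keep]; start <- start[keep]; end <- end[keep]
  strand <- strand[keep]
  p5 <- ifelse(strand == "+", start, end - 1L)

  if (spec$tissue != "none" && spec$depletion > 0) {
    expr <- spec$refs[[spec$tissue]]
    tssu <- unique(data.table::as.data.table(spec$tss)[,
                   .(gene_id, chrom, tss)])
    w_g <- rank(as.numeric(expr[tssu$gene_id])) / nrow(tssu)
    drop <- logical(length(p5))
    for (ch in unique(tssu$chrom)) {
      t_ch <- which(tssu$chrom == ch)
      f_ch <- which(chrom == ch)
      if (!length(t_ch) || !length(f_ch)) next
      ord <- order(tssu$tss[t_ch])
      starts <- tssu$tss[t_ch][ord] - flank
      ends <- tssu$tss[t_ch][ord] + flank
      # windows are disjoint by construction: locate each 5' end
      iv <- findInterval(p5[f_ch], starts)
      inwin <- iv >= 1L & p5[f_ch] < ends[pmax(iv, 1L)]
      gidx <- t_ch[ord][pmax(iv, 1L)]
      pdrop <- spec$depletion * w_g[gidx]
      drop[f_ch] <- inwin & stats::runif(length(f_ch)) < pdrop
    }
    chrom <- chrom[!drop]; start <- start[!drop]; end <- end[!drop]
    strand <- strand[!drop]
  }
  fr <- fragment_set(chrom, start, end, strand, genome)
  data.table::setattr(fr, "truth",
                      list(tissue = spec$tissue,
                           depletion = spec$depletion, seed = spec$seed))
  fr
}
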