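#' Read a per-subject chromosome z-score table
#'
#' TSV with a `subject_id` column and one column per chromosome
#' (`chr1..chr22, chrX, chrY`). `chrY` may be `NA` (female fetus) and is
#' then recorded as absent for that subject.
#'
#' @param path TSV file.
#' @return Named list of [chrom_zscores()] keyed by subject id.
#' @export
read_zscore_table <- function(path) {
  if (!file.exists(path)) stop("z-score table not found: ", path)
  dt <- data.table::fread(path, sep = "\t")
  needed <- c("subject_id", setdiff(chromosome_names(), "chrY"))
  missing <- setdiff(needed, names(dt))
  if (length(missing))
    stop("z-score table is missing required column(s): ",
         paste(missing, collapse = ", "))
  has_y <- "chrY" %in% names(dt)
  out <- lapply(seq_len(nrow(dt)), function(i) {
    z <- as.numeric(dt[i, setdiff(chromosome_names(), "chrY"), with = FALSE])
    names(z) <- setdiff(chromosome_names(), "chrY")
    if (has_y && !is.na(dt$chrY[i])) z <- c(z, chrY = as.numeric(dt$chrY[i]))
    chrom_zscores(z)
  })
  names(out) <- as.character(dt$subject_id)
  out
}

#' Write a z-score table (inverse of [read_zscore_table()])
#'
#' @param zlist Named list of [chrom_zscores()].
#' @param path Output TSV.
#' @export
write_zscore_table <- function(zlist, path) {
  cols <- chromosome_names()
  mat <- t(vapply(zlist, function(z) {
    v <- setNames(rep(NA_real_, length(cols)), cols)
    v[names(z)] <- as.numeric(z)
    v
  }, numeric(length(cols))))
  dt <- data.table::data.table(subject_id = names(zlist))
  dt <- cbind(dt, data.table::as.data.table(mat))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read per-cancer-type mean-FPKM expression references
#'
#' TSV with a `gene_id` column and one numeric column per cancer type
#' (e.g. BRCA, DLBC, LIHC mean FPKM).
#'
#' @param path TSV file.
#' @return Named list of `expression_reference` objects (one per column),
#'   each a named numeric vector of mean FPKM keyed by gene id.
#' @export
read_expression_reference <- function(path) {
  if (!file.exists(path)) stop("expression reference not found: ", path)
  dt <- data.table::fread(path, sep = "\t")
  if (!"gene_id" %in% names(dt))
    stop("expression reference needs a 'gene_id' column")
  if (anyDuplicated(dt$gene_id))
    stop("duplicated gene_id in expression reference: ",
         dt$gene_id[duplicated(dt$gene_id)][1L])
  types <- setdiff(names(dt), "gene_id")
  if (!length(types)) stop("expression reference has no cancer-type columns")
  out <- lapply(types, function(tp) {
    v <- dt[[tp]]
    if (!is.numeric(v)) stop("non-numeric FPKM values in column ", tp)
    if (any(is.na(v)) || any(v < 0))
      stop("negative or missing FPKM values in column ", tp)
    expression_reference(setNames(as.numeric(v), dt$gene_id), tp)
  })
  names(out) <- types
  out
}

#' Construct an expression reference
#'
#' @param fpkm Named nonnegative numeric vector (mean FPKM per gene).
#' @param cancer_type Label, e.g. `"LIHC"`.
#' @export
expression_reference <- function(fpkm, cancer_type) {
  if (is.null(names(fpkm)) || anyDuplicated(names(fpkm)))
    stop("fpkm must be named with unique gene ids")
  if (any(!is.finite(fpkm)) || any(fpkm < 0))
    stop("mean FPKM must be finite and >= 0")
  structure(fpkm, cancer_type = cancer_type,
            class = c("expression_reference", "numeric"))
}

#' Write expression references to TSV
#'
#' @param refs Named list of `expression_reference` sharing a gene set.
#' @param path Output TSV.
#' @export
write_expression_reference <- function(refs, path) {
  genes <- names(refs[[1L]])
  dt <- data.table::data.table(gene_id = genes)
  for (tp in names(refs)) dt[[tp]] <- as.numeric(refs[[tp]][genes])
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a TSS annotation table
#'
#' RefSeq-like TSV with columns `gene_id`, `transcript_id`, `chrom`, `tss`
#' (0-based position) and `strand`.
#'
#' @param path TSV file.
#' @return data.table of validated TSS records.
#' @export
read_tss_table <- function(path) {
  if (!file.exists(path)) stop("TSS table not found: ", path)
  dt <- data.table::fread(path, sep = "\t")
  needed <- c("gene_id", "transcript_id", "chrom", "tss", "strand")
  missing <- setdiff(needed, names(dt))
  if (length(missing))
    stop("TSS table missing column(s): ", paste(missing, collapse = ", "))
  validate_tss_table(dt)
}

validate_tss_table <- function(dt) {
  dt <- data.table::as.data.table(dt)
  if (any(dt$tss < 0)) stop("TSS positions must be >= 0")
  if (!all(dt$strand %in% c("+", "-"))) stop("TSS strand must be + or -")
  if (anyDuplicated(dt[, .(gene_id, transcript_id)]))
    stop("duplicated (gene_id, transcript_id) in TSS table")
  dt[]
}

#' Read a plasma tumor marker panel table
#'
#' CSV with `subject_id` plus one column per marker. Concentrations must be
#' nonnegative; missing values are rejected (no imputation).
#'
#' @param path CSV file.
#' @param markers Expected marker columns (default [default_ptm_cutoffs()]
#'   names).
#' @return Named list of [ptm_panel()] keyed by subject id.
#' @export
read_ptm_table <- function(path, markers = names(default_ptm_cutoffs())) {
  if (!file.exists(path)) stop("PTM table not found: ", path)
  dt <- data.table::fread(path)
  missing <- setdiff(c("subject_id", markers), names(dt))
  if (length(missing))
    stop("PTM table missing column(s): ", paste(missing, collapse = ", "))
  out <- lapply(seq_len(nrow(dt)), function(i) {
    v <- as.numeric(dt[i, markers, with = FALSE])
    names(v) <- markers
    ptm_panel(v)
  })
  names(out) <- as.character(dt$subject_id)
  out
}

#' Read a z-score reference panel
#'
#' TSV with columns `chrom`, `mean_fraction`, `sd_fraction`.
#'
#' @param path TSV file.
#' @return A [reference_panel()].
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  dt <- data.table::fread(path, sep = "\t")
  needed <- c("chrom", "mean_fraction", "sd_fraction")
  missing <- setdiff(needed, names(dt))
  if (length(missing))
    stop("panel missing column(s): ", paste(missing, collapse = ", "))
  reference_panel(setNames(dt$mean_fraction, dt$chrom),
                  setNames(dt$sd_fraction, dt$chrom))
}

#' @rdname read_panel
#' @param panel A [reference_panel()].
#' @export
write_panel <- function(panel, path) {
  dt <- data.table::data.table(
    chrom = names(panel$mean_fraction),
    mean_fraction = as.numeric(panel$mean_fraction),
    sd_fraction = as.numeric(panel$sd_fraction))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
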