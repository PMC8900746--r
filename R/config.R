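#' Pipeline configuration with published defaults
#'
#' Central container for every tunable cutoff and window parameter. Defaults
#' are the published values: MTOP5Zscores cutoff 5.94, MCA threshold |z| > 3,
#' the seven plasma-tumor-marker cutoffs, the 167 bp fragment extension with
#' its central 61 bp (offsets 53-113) nucleosome core, a TSS flank of
#' 1,000 bp each side, 100 kb copy-ratio bins, the RDPKM < 100 and
#' log2(mean FPKM) < 0.1 gene filters, and random-forest parameters
#' ntree = 500, mtry = floor(sqrt(32)) = 5.
#'
#' @param ... Named overrides of any default (see `str(pipeline_config())`).
#' @return A list of class `pipeline_config`.
#' @export
#' @examples
#' cfg <- pipeline_config(mtop5_cutoff = 6.5)
#' cfg$mtop5_cutoff
pipeline_config <- function(...) {
  defaults <- list(
    mtop5_cutoff      = 5.94,
    mca_threshold     = 3.0,
    mtop5_exclude     = c("chr19", "chrY"),
    ptm_cutoffs       = default_ptm_cutoffs(),
    extension_length  = 167L,
    core_offset_start = 53L,   # 1-based inclusive within the extension
    core_offset_end   = 113L,
    tss_flank         = 1000L,
    bin_size          = 100000L,
    ratio_clamp       = c(0.1, 10),
    rdpkm_min         = 100,
    log2_fpkm_min     = 0.1,
    rf_ntree          = 500L,
    rf_mtry           = 5L,
    rf_seed           = 1L
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
    defaults <- utils::modifyList(defaults, overrides)
  }
  validate_pipeline_config(defaults)
  structure(defaults, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  num_fields <- c("mtop5_cutoff", "mca_threshold", "tss_flank", "bin_size",
                  "rdpkm_min", "log2_fpkm_min")
  for (f in num_fields)
    if (!is.numeric(cfg[[f]]) || !all(is.finite(cfg[[f]])))
      stop("config field '", f, "' must be finite numeric")
  if (any(!is.finite(cfg$ptm_cutoffs)) || any(cfg$ptm_cutoffs <= 0))
    stop("PTM cutoffs must be positive")
  span <- cfg$core_offset_end - cfg$core_offset_start + 1L
  if (span < 1L || cfg$core_offset_end > cfg$extension_length)
    stop("core offsets must lie within the extension length")
  if (cfg$rf_ntree < 1L || cfg$rf_mtry < 1L)
    stop("random-forest parameters must be positive")
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#'
#' Only fields present in the file override the defaults, so a config file
#' can be sparse.
#'
#' @param path YAML file path.
#' @return `read_config`: a `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  if (!is.null(vals$ptm_cutoffs)) vals$ptm_cutoffs <- unlist(vals$ptm_cutoffs)
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @param cfg A `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  vals <- unclass(cfg)
  vals$ptm_cutoffs <- as.list(vals$ptm_cutoffs)  # yaml map keeps names
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat("  MTOP5Zscores cutoff:", x$mtop5_cutoff,
      " | MCA |z| threshold:", x$mca_threshold, "\n")
  cat("  nucleosome core: offsets", x$core_offset_start, "-",
      x$core_offset_end, "of", x$extension_length, "bp extension\n")
  cat("  TSS flank:", x$tss_flank, "bp | bins:", x$bin_size, "bp\n")
  cat("  filters: RDPKM >=", x$rdpkm_min, ", log2(FPKM) >=",
      x$log2_fpkm_min, "\n")
  cat("  random forest: ntree =", x$rf_ntree, ", mtry =", x$rf_mtry, "\n")
  invisible(x)
}
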