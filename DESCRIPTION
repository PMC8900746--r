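Package: mcanary
Title: Occult Maternal Malignancy Detection from NIPT Cell-Free DNA
Version: 0.1.0
Authors@R:
    person("mcanary", "developers", email = "mcanary@example.org",
           role = c("aut", "cre"))
Description: Detects occult maternal malignancy in noninvasive prenatal
    testing (NIPT) shallow cell-free DNA sequencing data. Computes
    per-chromosome z-scores from binned fragment counts against a
    reference panel, flags multiple chromosomal aneuploidies (MCA),
    and scores subjects with the MTOP5Zscores cancer predictor (mean
    of the top five absolute chromosome z-scores excluding chrY and
    chr19, cutoff 5.94). A tissue-of-origin layer quantifies
    nucleosome-footprint coverage around transcription start sites
    (RDPKM), correlates it with tumor expression references via
    normalized Pearson correlation coefficients (NPCC), screens seven
    plasma tumor markers, and classifies the primary tumor (breast,
    gastric, liver, lymphoma) with a bagged Gini random forest
    evaluated by leave-one-out cross-validation. A synthetic cohort
    generator reproduces the published per-cancer-type chromosome
    gain/loss frequencies, the chr19 technical artifact, tumor marker
    elevations, and expression-anticorrelated TSS coverage so the
    whole pipeline is testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    methods,
    IRanges,
    S4Vectors,
    Rsamtools,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
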