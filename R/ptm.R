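#' Default plasma tumor marker cutoffs
#'
#' Seven markers with the assay manufacturer's cutoffs: CA15-3 28 U/ml,
#' AFP 500 ng/ml, CEA 5 ng/ml, CA19-9 37 U/ml, CA125 36 U/ml, and 3.3 /
#' 1.2 ng/ml for the last two panel positions. The published marker list
#' and cutoff list disagree on the final two names (CA72-4/CYFRA21-1 vs
#' CYFRA21-1/SCC), so names are configuration data; the defaults pair the
#' seven printed cutoffs positionally with the marker-list names.
#'
#' @return Named numeric vector of cutoffs in panel order.
#' @export
default_ptm_cutoffs <- function() {
  c(`CA15-3` = 28, AFP = 500, CEA = 5, `CA19-9` = 37, CA125 = 36,
    `CA72-4` = 3.3, `CYFRA21-1` = 1.2)
}

#' A plasma tumor marker panel measurement
#'
#' @param conc Named nonnegative numeric vector of exactly seven marker
#'   concentrations.
#' @return A `ptm_panel`.
#' @export
ptm_panel <- function(conc) {
  if (is.null(names(conc))) stop("PTM concentrations must be named")
  if (length(conc) != 7L) stop("PTM panel must have exactly 7 markers")
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("PTM concentrations must be finite and >= 0 (no imputation of ",
         "missing values)")
  structure(as.numeric(conc), names = names(conc),
            class = c("ptm_panel", "numeric"))
}

#' Any-marker plasma tumor marker screening rule
#'
#' A subject is at high risk when the concentration of at least one marker
#' strictly exceeds its prespecified cutoff; equality is negative.
#'
#' @param panel A [ptm_panel()].
#' @param cutoffs Named cutoffs covering exactly the panel's markers
#'   (default [default_ptm_cutoffs()]).
#' @return Logical flag with attribute `exceeding` (character vector of
#'   markers above cutoff, in panel order).
#' @export
flag_ptm_high_risk <- function(panel, cutoffs = default_ptm_cutoffs()) {
  if (!setequal(names(panel), names(cutoffs)))
    stop("PTM panel and cutoffs must cover identical marker sets")
  cutoffs <- cutoffs[names(panel)]
  over <- panel > cutoffs
  structure(any(over), exceeding = names(panel)[over])
}
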