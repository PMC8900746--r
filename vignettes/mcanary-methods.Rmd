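---
title: "mcanary: models, parameters, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mcanary: models, parameters, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the statistical model at each stage, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the places where
the published description was ambiguous and a design decision had to be
made. It states no empirical result that the test-suite or
`scripts/acceptance.R` does not itself compute.

## 1. Chromosome z-scores and the MCA flag

A subject's per-chromosome z-score standardizes the chromosome's share of
total cfDNA fragments against a reference panel:
`z_c = (f_c − μ_c) / σ_c`, with `f_c` the sample fraction and
`(μ_c, σ_c)` panel mean and SD. NIPT providers export such z-scores
directly; `read_zscore_table()` consumes them, and the fraction-based
engine (`chromosome_fractions()` → `compute_zscores()`) exists so
fragment-level input can be scored against a user-supplied panel. No GC
correction is applied here: commercial pipelines differ in their
normalizations, the downstream statistics consume z-scores whatever
produced them, and the one GC-driven artifact that matters downstream
(chr19) is modeled explicitly in the simulator instead.

**MCA** (multiple chromosomal aneuploidies) is at least two chromosomes
with |z| strictly greater than 3.0. The inequality is strict as printed:
a chromosome at exactly 3.0 does not count. chrY participates in the MCA
count when defined (male fetus) and is simply absent otherwise; whether
the original definition includes the sex chromosomes is unstated, and
applying the rule to every chromosome with a defined z is the reading
that needs no extra assumption.

## 2. MTOP5Zscores

The cancer predictor is the mean of the five largest absolute z-scores
over the 22 candidates (chr1–18, chr20–22, chrX). Two chromosomes are
excluded:

* **chrY** — fetal-sex dependent, undefined for half of pregnancies;
* **chr19** — a technical artifact in this assay class: in non-cancer
  NIPT samples chr19 "deletions" occur at 53.92% and "amplifications" at
  21.89%, so chr19 would dominate the top-5 in healthy subjects. The
  exclusion list is configuration (`pipeline_config(mtop5_exclude=)`),
  since the artifact rate is cohort- and pipeline-specific.

**Absolute vs signed mean.** The source description ("mean of the top
five chromosome z scores", selected by largest absolute value) does not
print a worked score. The package averages the *absolute* values: a
signed mean would let deletions cancel amplifications, and a
deletion-dominated cancer (the liver profile, where the most frequent
events are deletions) could never cross the positive cutoff 5.94 — the
signed reading is internally inconsistent with the published cutoff, so
it was rejected.

Classification is strictly greater-than the cutoff (default 5.94); a
score exactly at the cutoff is negative. Ties at the fifth rank do not
affect the score (the tied values are equal); only the reported
`contributing` list needs a rule, and it breaks ties by canonical
chromosome order so output is deterministic.

## 3. Nucleosome-footprint TSS coverage

cfDNA fragmentation preserves nucleosome footprints: actively
transcribed genes have nucleosome-depleted promoters, so cfDNA coverage
around their TSS is reduced in proportion to expression *in the tissue
releasing the DNA*. The pipeline:

1. **5′ ends.** Each read contributes its 5′ terminus; reverse reads use
   start + length − 1 (i.e. `end − 1` in the package's 0-based half-open
   convention). Internal coordinates are 0-based half-open everywhere,
   with SAM/BAM's 1-based closed coordinates converted at the boundary —
   a single convention avoids the off-by-one family of bugs in the
   window arithmetic below. Records are treated as reads, not templates
   (the 5′-adjustment is defined read-wise; a paired-end BAM yields one
   record per read).
2. **Core windows.** The 5′ end is extended to the canonical 167 bp
   mononucleosome fragment span and the central 61 bp kept — 1-based
   offsets 53–113 within the extension, i.e. `[s+52, s+113)` on the
   forward strand and its mirror image on the reverse. Windows
   protruding past a chromosome edge are dropped and counted.
3. **Copy-ratio normalization.** Per-base depth is divided by the local
   copy ratio so tumor CNVs do not masquerade as expression signal.
   Ratios come from 100 kb bins of 5′-end counts over the median
   non-empty autosomal bin, clamped to [0.1, 10]. Two deliberate
   simplifications:
   * the published pipeline used an HMM copy-number caller at the same
     resolution; only the per-bin ratio feeds the normalization, and at
     this package's scale the HMM's segmentation smoothing adds nothing
     testable, so median-ratio bins replace it (configurable bin size);
   * "dividing read depth by median log2 scaled copy-number variation
     ratio" is ill-defined read literally — a log2 ratio is 0 at neutral
     copy number (division by zero) and negative in deletions. The
     implementation divides by the *linear* ratio `2^log2ratio`, the
     only numerically sane reading that removes CNV bias; the clamp
     guarantees a safe divisor.
4. **RDPKM.** Depth is accumulated over TSS ± 1,000 bp and normalized as
   read depth per kilobase per million mapped reads:
   `RDPKM = Σdepth / (window_kb × total_mapped/10⁶)`. "1,000 flanking
   regions around the TSS" is read as ±1,000 bp (a 2 kb window): the
   only interpretation consistent with per-kilobase normalization of a
   TSS-centered window. Genes with several transcripts take the mean
   transcript RDPKM. Windows partially off-chromosome skip the
   transcript (logged), never truncate silently.
5. **Gene filters.** Genes with RDPKM < 100 (unreliable coverage) or
   log2(mean FPKM) < 0.1 in any reference (near-silent) are eliminated;
   both rules are strict `<` as printed, so boundary values are
   retained. The published "mean of 14,589 genes" is a cohort-specific
   count, not a constraint; the per-sample `n_genes_used` is reported
   instead.

## 4. NPCC

For reference cancer types i ∈ {BRCA, DLBC, LIHC} (any set of
mean-FPKM tables works; the three defaults mirror the published
references), `R_i = cor(RDPKM, FPKM_i)` over the retained genes and
`NPCC_i = R_i / Σ_j R_j`. The raw correlations are expected negative
(footprint anticorrelation), and the matching tissue the most negative;
normalization then makes the matching component the largest positive
share, summing to 1 exactly. Degenerate inputs error rather than
propagate: fewer than 3 retained genes, a constant vector on the
retained set, or |ΣR| < 1e-8 (coefficients cancelling makes the
normalization meaningless).

## 5. Plasma tumor markers

Seven markers with fixed clinical cutoffs; a subject is high-risk when
at least one concentration *strictly* exceeds its cutoff. The published
marker list and cutoff list disagree on the last two names
(CA72-4/CYFRA21-1 vs CYFRA21-1/SCC), so marker names are configuration
data and the defaults pair the seven printed cutoffs positionally with
the marker-list names: CA15-3 28 U/ml, AFP 500 ng/ml, CEA 5 ng/ml,
CA19-9 37 U/ml, CA125 36 U/ml, CA72-4 3.3 ng/ml, CYFRA21-1 1.2 ng/ml.
Missing marker values are rejected, never imputed — subjects without a
PTM panel are excluded from classification, as the published n = 42
classifier table implies.

## 6. Tissue-of-origin classifier

Feature vector (fixed canonical order): 3 NPCC values, z-scores of the
22 autosomes, 7 PTM concentrations. "z scores of 22 chromosomes" is read
as the autosomes — chr19 *included* (its exclusion applies only to
MTOP5Zscores, and chr19 amplification is genuinely informative for
lymphoma and gastric profiles), chrX excluded.

The forest is the classic bagged-CART classifier: 500 trees grown to
purity on bootstrap samples, Gini impurity splitting, mtry = ⌊√32⌋ = 5
(the classification default of the reference implementation, pinned in
configuration rather than left to a library so results are portable),
vote-fraction probabilities, MeanDecreaseGini importance (per-tree mean
of each feature's total `n·Gini` decrease). The environment provides no
random-forest package, so the backend is implemented in compiled code
within the package, with a self-contained 64-bit RNG — identical output
for identical seeds on any platform. No class weighting or resampling is
applied despite the 15/7/12/8 imbalance, matching the published plain
call.

LOOCV re-seeds each fold deterministically (`seed + fold`), so the whole
cross-validation is one reproducible computation. Per-class ROC/AUC uses
the held-out class probability as score.

## 7. Evaluation machinery

* **Confusion matrices** are predicted × truth; one-vs-rest collapse
  gives TP/FN/FP/TN per class. Zero-denominator metrics are reported as
  undefined (`NA`), never as 0.
* **Confidence intervals** are exact Clopper–Pearson (beta quantiles).
  The published tables do not name their CI method; Clopper–Pearson
  reproduces the printed interval for 36/42 (71.46–94.57%) where Wilson
  does not, which settles the choice. (One printed interval is
  internally inconsistent between table and prose — 88.28 vs 86.28 for
  the validation specificity upper bound; the exact CP value of 112/140
  matches the prose, and nothing is pinned to that number.)
* **ROC/AUC**: scores are swept with the rule "positive iff
  score > threshold"; AUC is the Mann–Whitney U-statistic normalized by
  `n₁n₀` with ties counted ½, verified in the tests against a
  brute-force pairwise oracle, and invariant under strictly monotone
  score transforms.
* **Optimal cutoff**: the criterion behind the published 5.94 is
  unstated; Youden's J (TPR − FPR) is the standard "optimal cutoff" of
  the common ROC tooling and is used here, with ties broken toward the
  higher threshold (higher specificity). Returned cutoffs are midpoints
  between adjacent observed scores, so separable groups get a cutoff
  strictly inside the gap.

## 8. The synthetic cohort: what it is and is not

The generator's defaults are the published conditions wherever a number
is printed, and documented placeholders where only a floor is printed:

* liver amplification/deletion frequencies are the printed values
  (chr20 69.2%, chr1/2/6/7 61.5%; chr4 92.3%, chr18 69.2%, chr13/16
  61.5%, chr15 53.8%);
* breast / lymphoma / gastric top-5 chromosomes are printed only as
  ">50%", ">44.4%", ">42.9%": placeholders 0.55 / 0.50 / 0.48;
  remaining per-chromosome probabilities default to 0 and are free
  configuration;
* the non-cancer arm gets only baseline noise plus the chr19 artifact
  (deletion 0.5392, amplification 0.2189);
* class sizes default to the published classifier table totals
  (15/7/12/8) plus 400 controls.

Chromosome events are independent across chromosomes — only marginal
frequencies were published, and inventing a co-occurrence structure
would be fiction. Affected chromosomes draw |z| from 3.2 + Gamma(2, 1.5)
(so "affected" reliably means |z| > 3; no z magnitudes are printed, and
the shape/scale are configuration). Baseline noise is N(0, 1.5): this
cohort is MCA-*enriched* by enrollment, so its residual chromosome noise
is wider than the unit SD a pure euploid panel would show; 1.5 makes a
second |z| > 3 chromosome common without crossing the MTOP5 cutoff, the
qualitative behavior the screening table implies.

PTM panels are log-normal (scale 0.5 per marker). The non-cancer
location is pinned analytically to the published any-marker specificity
(93.13% → equal per-marker tail 1 − 0.9313^(1/7)), and the cancer
"driver" shift (AFP for liver; CA15-3/CA125/CEA for breast;
CA72-4/CEA/CA19-9 for gastric; CYFRA21-1 for lymphoma; 0.3 for
non-drivers) is solved by uniroot so the class-weighted any-marker
sensitivity equals the published 66.07%. This calibration is closed-form
and happens in the spec constructor before any draw — nothing is tuned
against simulated outcomes.

Fragment sets are uniform background reads (length N(167, 10)) with CNV
segments scaling the local rate and TSS ± 1 kb windows thinned by
`depletion × expression_rank` in the chosen tissue; expression
references are log-normal with a shared baseline and a disjoint
high-expression block per type. Defaults (toy 3 Mb genome, 150,000
fragments, depletion 0.7) give roughly 3× nucleosome-core coverage — a
shallow-WGS-like regime scaled to the toy genome — and are chosen once,
for realism and runtime, not against test outcomes.

**What a green test does not establish.** The generator reproduces
printed *marginal* frequencies and operating points, not the joint
structure of real tumor genomes: no co-occurring CNV patterns, no GC
bias curves, no fetal-fraction variation, no sequencing error, no
mosaicism, and z-effect magnitudes far cleaner than clinical reality
(the synthetic MTOP5 AUC saturates near 1, versus ~0.9 published).
Passing acceptance therefore validates the *pipeline arithmetic and its
operating behavior under the stated world*, not clinical performance.
Conversely the chance-level LOOCV check runs on pure noise, where LOOCV
with balanced classes is known to be pessimistically biased below 1/k
(holding out a sample unbalances its own class in training), so that
check uses an a-priori band around 0.25 rather than a tight equality.

One test-design note: "separable classes" for forest sanity checks are
built with per-class *blocks* of elevated features. A lone marker
feature per class drowned in 28 noise columns defeats any
reference-grade forest at n = 12 (verified against an independent
implementation during development) — that is a property of the data
design, not of the backend.

## 9. Known limitations

* The z-score engine is the standard fraction-based formulation with a
  user-supplied panel; it does not reimplement any vendor's proprietary
  normalization. Real NIPT z-scores should enter through the table
  reader.
* The copy-ratio normalization is bin-median based; highly aneuploid
  genomes where more than half the autosomal bins are altered would
  shift the median and re-scale ratios globally.
* NPCC is restricted to the reference types supplied; a tumor of any
  other origin projects onto them.
* The classifier is exactly the published 32-feature plain forest: no
  calibration, no class weights, no hyperparameter search, and the
  published gastric weakness is expected to persist.
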