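---
title: "Methods: PDE4D isoform-switch signatures and their evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PDE4D isoform-switch signatures and their evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoswitchr)
library(dplyr)
```

This vignette is the package's own account of the models and numerical
choices behind each stage. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## Isoform quantification

Exon-array expression of a transcript isoform is measured by the mean
log2 intensity of its isoform-specific probesets (the alternative first
exons distinguish the isoforms; PDE4D1 and PDE4D2 share one probeset
and are therefore reported as the joint channel `PDE4D1/2`). The
normalization factor of a sample is computed in two levels: probesets
are averaged **within** each reference gene (HPRT1, PUM1, TBP, POLR2A,
TUBA1B), and the per-gene estimates are then averaged. The order
matters when genes carry unequal probeset counts, so the flat
probeset mean is deliberately not used. The factor is subtracted from
every probeset before averaging per isoform, which makes the profile —
and hence both signatures — exactly invariant to any per-sample global
shift (array brightness, loading). `summarize_isoforms()` raises a hard
error on missing probesets rather than imputing: the signatures are
differences of a handful of terms and any imputation would bias them
directly.

qPCR data are normalized as `mean(Ct(reference panel)) - Ct(target)`,
which is antitone in the target Ct; biopsy profiles are re-expressed in
linear fold space via `2^(delta)` relative to the within-tumour biopsy
of the same patient (so the tumour maps to exactly 1), then summarized
per location as mean ± SEM. RNA-seq scaled estimates convert to
transcripts per million by multiplication with 1e6.

## Signatures and their evaluation

The diagnostic score is `PDE4D7 - PDE4D5`; the prognostic score is
`PDE4D1/2 - (PDE4D5 + PDE4D7 + PDE4D9)`. Orientation is fixed, not
fitted: higher diagnostic score means more tumour-like, higher
prognostic score means worse prognosis, and the reported AUC is for
that stated orientation without auto-flipping. The AUC is the
Mann–Whitney statistic (ties receive half credit, implemented through
average ranks). Group comparisons use a two-sided
Wilcoxon–Mann–Whitney test: for combined n ≤ 20 the p-value is
computed by exhaustive enumeration of all rank splits — exact even
with ties, which the classical exact algorithm does not handle — and
larger samples use the normal approximation with tie-corrected
variance. The cutoff at 20 is a tractability choice
(`C(20, 10) = 184756` splits) and is recorded in the result's `method`
column.

## PAM dichotomization

ERG status and signature high/low groups come from k-medoids (k = 2)
on one-dimensional values under absolute distance. For n ≤ 500 the
optimum is found by scanning all `C(n, 2)` medoid pairs; the
BUILD + SWAP iteration is kept for larger inputs and k > 2, and the
test suite checks it reaches the exhaustive optimum. Cost ties are
genuine in one dimension — any value between the two middle order
statistics of an even-sized cluster yields the same absolute-deviation
sum — so ties are broken toward the lexicographically smallest medoid
values, which makes results invariant to input order. `label_clusters()`
names the cluster with the larger medoid "high" (or "positive") and
refuses to label when both medoids are equal.

## Peak enrichment

Intervals are 0-based half-open everywhere internally and on BED
input/output. A peak counts for a region when they share at least one
base. The empirical null for a target locus is the distribution of peak
counts over background regions — decoy gene loci or random windows —
and the report is the inclusive ECDF percentile
`100 * #{background <= observed} / N`, which yields 100 for maxima
(consistent with reporting percentiles above 99.99 rather than capping).
Random windows follow `number of windows = chromosome size in Mb x 1000`
per chromosome (`floor(size_bp / 1000)`; on the hg19 major chromosomes
this exceeds three million 1.5 Mb windows), with independent uniform
starts; windows overlapping the excluded locus are removed *after*
sampling, without resampling. TSS windows are strand-aware: the TSS is
`start` on the plus strand and `end - 1` on the minus strand, and the
window covers the flank on both sides of that base (the minus-strand
half-open window is therefore one base longer, matching the mirrored
transcript-relative span). Nearest-peak distances are genomic gaps with
overlapping or abutting features at distance 0.

One numerical caveat documented here because it shapes the calibration
test: with small expected counts the percentile lives on the lattice of
the count distribution, so its null distribution is only approximately
uniform. The uniformity check in the test suite therefore uses an
expected background count of about 100 per region, where the lattice
spacing is fine relative to the resolution of a 500-replicate
Kolmogorov–Smirnov test.

## Differential methylation

Three modalities share one calling skeleton (select, then merge):

- **Binned counts** (MeDIP-style): counts are summed into half-open
  100-nt bins and group-summed per bin. Equality of the two group rates
  is tested conditionally on the bin total — an exact binomial test of
  the case share against the library-size expectation — with Bonferroni
  adjustment over the bins actually tested (non-zero total), flagging
  adjusted p < 0.01. Directly adjacent flagged bins of the same
  direction merge.
- **Per-position fractions** (bisulfite): methylation is
  `#C / (#C + #T)`; zero-coverage positions are skipped with a note.
  Per position, a two-sided rank test compares per-sample fractions,
  Benjamini–Hochberg controls FDR at 0.05, and flagged positions within
  100 nt of each other merge.
- **Beta values** (array): probes with |case mean − control mean| ≥
  0.15 are candidates; consecutive same-direction candidates merge into
  regions scored by the summed differences, and significance comes from
  100 group-label permutations compared against the permutation
  distribution of the genome-wide maximum absolute region score.

These are deliberately self-contained stand-ins for the
package-specific tests used in typical array/sequencing workflows
(edgeR, limma, bumphunter): the selection thresholds and merging rules
are retained, and concordance with those packages is not claimed.
Hyper-methylation means the case mean exceeds the control mean; regions
of opposite direction never merge. Region methylation is related to
isoform expression by Spearman correlation (average ranks), where
promoter silencing appears as negative rho.

## Copy number and survival

Copy-number calls use the symmetric cutoff ±log2(1.5/2) ≈ ±0.415
(inclusive at the cutoff). Kaplan–Meier curves, the two-group log-rank
test and Cox proportional-hazards fits are computed with the standard
partial-likelihood machinery of the survival package behind the
package's tidy interfaces; `cox_fit()` reports non-convergence and
degenerate (constant) covariates explicitly rather than silently.
`evaluate_prognostic()` composes score → PAM → KM/log-rank/Cox and
flags unstable groupings (a cluster with fewer than two samples). Plain
right-censored analysis is the default; an optional follow-up `horizon`
censors events beyond a time limit, provided as the closest defensible
reading of truncated-follow-up analyses — genuine left-censoring is not
meaningful for post-surgery follow-up data, so it is not implemented.
Cox results annotate significance at both 0.05 and 0.1 through the
reported p-values.

## The synthetic-data generators

The generators define the conditions every test runs under; they are
first-class, tested code, not fixtures.

- **Expression** (`gen_expression_cohort()`): Gaussian noise in log2
  space (the natural model for RMA-scale array data) around planted
  per-group channel means, one shared per-sample offset applied to all
  probesets including references (so the normalization provably removes
  it), flat reference genes, and auxiliary PCA3/ERG/PART1 channels with
  a per-sample ERG-fusion upshift in tumour groups. The default means
  encode the qualitative switch ordering (PDE4D7 up in primary tumours
  then down; PDE4D5/PDE4D9 monotone down; PDE4D1/2 flat) with shifts of
  0.8–2.5 log2 units and a within-group standard deviation of 0.5 log2
  units per probeset — magnitudes chosen once as typical array-scale
  values; the ordering, not the magnitudes, is the modelled claim.
- **Peaks** (`gen_peaks_and_loci()`): homogeneous Poisson placement at
  the background rate genome-wide plus an independent Poisson excess in
  the target locus, so decoy-locus counts are exact background draws.
  Decoys are non-overlapping region-length slots sampled without
  replacement.
- **Methylation** (`gen_methylation()`): Poisson coverage and binomial
  methylated-base counts, with the success probability raised by a
  planted delta inside the DMR interval for the case group only. The
  methylated-read counts double as MeDIP-style bin counts when testing
  the count mode.
- **Survival** (`gen_survival()`): exponential proportional hazards
  with linear predictor `hazard_coef * score` and independent
  exponential censoring.

Determinism is a contract: equal seeds give byte-identical outputs,
and the pipeline writes provenance JSON (inputs, parameters, seed,
version) next to every artifact.

**What passing tests show — and what they do not.** The synthetic
cohorts are *cleaner* than real ones: within-group spread is pure
measurement noise, with no patient-level biological heterogeneity,
batch structure, cross-hybridization or outlier samples. Planted
effects of 1.5–2.5 log2 units against 0.5 log2 noise make the
diagnostic AUC approach 1, where published cohorts report AUCs in the
0.8–0.95 range. The tests therefore verify the *machinery* — that each
estimator recovers what was planted, at the stated error rates — and
the qualitative structure (diagnostic AUC > 0.8, significant high/low
survival separation), not any real-data performance number.

## Problem sizes and numerical choices

The default test and acceptance runs use cohorts of 12–200 samples per
group, methylation tracks of 60–200 positions at depth 30–100,
enrichment genomes of one 50–180 Mb chromosome with 25–150 decoy loci
(the acceptance script uses the full hg19 table with 2000 decoys and
the complete >3 million-window budget), 100 beta permutations, and
20–500 replicate seeds for calibration checks — sizes at which the
asymptotic properties under test are expected to hold while a full run
stays comfortably on one CPU. Tolerances: exact-arithmetic checks at
machine precision; stochastic recoveries at 2–3 standard errors of the
relevant estimator; calibration via Kolmogorov–Smirnov at alpha 0.01.
Ties: average ranks throughout; PAM ties as described above; ECDF
inclusive. Degenerate inputs (empty groups, constant vectors,
zero coverage, equal medoids, single-class labels) raise typed errors
or documented NA-with-warning results rather than silent values.

## Known limitations

- Raw CEL/RMA processing, probeset design, batch correction and genome
  liftover are out of scope; inputs are assumed normalized and on one
  build.
- The methylation stand-in tests are calibrated but are not the
  published package pipelines; borderline regions can differ.
- The exact Wilcoxon enumeration is limited to combined n ≤ 20.
- `pam_1d()` is specialized to one dimension; k > 2 uses the heuristic
  BUILD + SWAP path without optimality guarantees.
- The survival generator draws exponential event times; it plants
  proportional hazards but not time-varying effects or competing risks.
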