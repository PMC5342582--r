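# isoswitchr

Transcript-isoform switching signatures for prostate cancer, built
around the phosphodiesterase 4D (PDE4D) gene.

## The problem

PDE4D expresses nine major transcript isoforms from alternative
promoters. In prostate tissue their composition shifts in a
characteristic way: the long isoform PDE4D7 is up-regulated in
localized prostate cancer and falls again with progression, while
PDE4D5 and PDE4D9 decline monotonically from benign tissue through
castration-resistant disease, and the super-short PDE4D1/2 channel
stays roughly flat. Two simple contrasts of reference-normalized log2
expression exploit this switch:

- **diagnostic score** `PDE4D7 - PDE4D5` — separates tumour from
  normal adjacent prostate (higher = more tumour-like);
- **prognostic score** `PDE4D1/2 - (PDE4D5 + PDE4D7 + PDE4D9)` —
  tracks the loss of long isoforms with progression (higher = worse
  prognosis).

`isoswitchr` implements the full computational pipeline around these
scores for analysts working with exon-array probeset intensities or
qPCR Ct tables:

- probeset-to-isoform summarization with two-level reference-gene
  normalization (probesets averaged within gene, genes averaged into a
  per-sample factor that is subtracted from every probeset);
- qPCR normalization `mean(Ct(reference genes)) - Ct(target)`,
  tumour-relative fold changes `2^dCt` and per-location mean ± SEM
  biopsy profiles;
- rank-based ROC/AUC and exact Wilcoxon–Mann–Whitney group comparisons;
- unsupervised dichotomization (ERG status, signature high/low) by
  one-dimensional partitioning around medoids, solved exactly for k = 2;
- transcription-factor peak enrichment in a gene locus against
  empirical nulls built from decoy gene loci or random genomic windows
  (`number of windows = chromosome size in Mb x 1000`, 1.5 Mb each),
  reported as ECDF percentiles, plus TSS ± 2 kb overlaps and
  nearest-peak distances;
- differential-methylation calling on three modalities (binned read
  counts with an exact conditional rate test and Bonferroni < 0.01;
  per-position C/(C+T) fractions with rank tests and FDR < 0.05,
  merged within 100 nt; array beta values with a 0.15 cutoff and
  permutation assessment), plus Spearman correlation of region
  methylation with isoform expression;
- copy-number calls at the ±log2(1.5/2) cutoff and Kaplan–Meier /
  log-rank / Cox evaluation of the prognostic signature;
- a synthetic-cohort generator that plants every one of these effects
  (group-shifted log-normal expression, a shared per-sample
  normalization offset, Poisson peak enrichment, binomial methylation
  with a planted DMR, exponential proportional-hazards survival) so the
  whole pipeline is testable against ground truth.

Everything takes and returns tibbles and composes with the pipe;
result objects have `tidy()`/`glance()` methods and `autoplot()`
figures.

## Worked example

```r
library(isoswitchr)
library(dplyr)

# a synthetic four-condition cohort with the planted isoform switch
spec   <- cohort_spec(n_per_group = 100, seed = 42)
cohort <- gen_expression_cohort(spec)

profile <- summarize_isoforms(cohort$intensities, cohort$map)

# diagnostic signature: tumour vs normal adjacent prostate
scores <- diagnostic_score(profile)
labels <- cohort$samples %>%
  filter(group %in% c("NAP", "PCa")) %>%
  transmute(sample_id, label = group)
evaluate_signature(scores, labels, positive = "PCa")
#> Signature evaluation: AUC = 1.000 (100 positive 'PCa' vs 100 negative), Wilcoxon p = 2.56e-34

# prognostic signature: survival with hazard tied to the score
prog    <- prognostic_score(profile)
records <- gen_survival(prog, hazard_coef = 1, censor_rate = 0.02, seed = 7)
outcome <- evaluate_prognostic(profile, records %>% select(sample_id, time, event))
glance(outcome)
#> # A tibble: 1 × 6
#>   n_high n_low logrank_p cox_hr    cox_p unstable_grouping
#>    <int> <int>     <dbl>  <dbl>    <dbl> <lgl>
#> 1    200   200  1.03e-96   2.80 1.90e-81 FALSE
```

The AUC of 1.000 says the planted tumour-vs-benign shift (2.5 log2
units against 0.5 log2 units of probeset noise) is fully separable at
this cohort size; `logrank_p` and `cox_hr` show the PAM-defined
signature-high group carries the planted excess hazard (true hazard
ratio e^1 ≈ 2.72 per unit score). Real cohorts are noisier; the methods
vignette discusses what these synthetic numbers do and do not show.

`run_pipeline(pipeline_config(), "out/")` executes every stage
(simulate → quantify → score → group → enrich → dmr → survival) with
the standard thresholds, writing TSV/JSON/BED artifacts, each with a
JSON provenance record; reruns with the same configuration are
byte-identical.

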