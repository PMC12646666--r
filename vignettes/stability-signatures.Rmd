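---
title: "Stability-selected gene signatures: methods and design"
author: "stabsig authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability-selected gene signatures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical procedure the package implements,
the defaults it ships with and why, what the synthetic cohort generator does
and does not emulate, and the numerical decisions taken where the design was
genuinely open. It states no empirical results beyond what the test suite
and `scripts/acceptance.R` themselves compute.

## The setting

The input is a genes × samples matrix of raw bulk RNA-seq counts from
whole blood, plus per-sample clinical metadata: study, arm (treated,
placebo, or untreated control), a binary responder/nonresponder (R/NR)
label for treated samples, and continuous outcomes — C-peptide AUC as a
percentage of its pre-treatment baseline (measured at months 6 and 12), and
time to diagnosis in months. The goal is a compact gene set whose weighted
expression sum (the *response score*) predicts the response label.

## Preprocessing

**Size factors.** `medianOfRatiosSizeFactors()` implements the
median-of-ratios estimator: for sample *j*, the median over reference genes
of `counts[g, j] / geomean_g`, where the reference set is the genes with
all-positive counts. Both the raw factors and factors rescaled to a unit
geometric mean are returned; normalization divides by the raw factors, the
convention of the standard estimator. The median is taken on the ratio
scale, so with an even reference-gene count the central pair is averaged
arithmetically; the widely used log-scale variant averages geometrically,
an O(10⁻⁵) relative difference that the test suite pins down explicitly.

**Expression filter.** A gene is kept when it has ≥ 10 counts in ≥ 40% of
samples. Both thresholds are inclusive — the only reading consistent with
"at least" and "a minimum of" — and the fraction comparison is exact
(`k/n >= 0.40` with no rounding), which matters when 40% of an odd sample
count is fractional.

**Batch stage.** Batch integration is a pluggable contract executed on raw
counts *before* normalization and filtering (mirroring the standard
ComBat-seq → size factors → filter order). Three methods are provided:
`none` (identity), `median-center` (per-gene multiplicative rescaling so
batch-wise gene medians match the global gene median, rounded to integers
and floored at zero — sufficient location alignment for the rank- and
correlation-based statistics downstream), and `external` (pass-through of a
matrix adjusted by any external tool, shape-checked). An empirical-Bayes
negative-binomial batch model is deliberately out of scope.

## Signature derivation

**Wilcoxon markers.** `wilcoxonDE()` tests a gene when it is detected
(value > 0) in ≥ 25% of either group. The two-sided p-value uses exact null
enumeration when both groups have ≤ 8 units and the gene is tie-free
(verified against full enumeration in the tests), and the normal
approximation with tie and continuity corrections otherwise. Bonferroni
adjustment is over tested genes only. Ranking for the top-k signature is by
|standardized W| (the tie-corrected z of the rank sum) — discriminatory
power, not fold change — with ties broken by larger |log2 FC| and then
lexicographic gene id so results are deterministic. The log2 fold change
uses a pseudocount of 1 on group means, chosen for robustness at zero
means. Mitochondrial/ribosomal exclusion is left to the caller as a plain
gene-id filter, since identifier conventions vary across references.

**Correlation signatures.** `pearsonSignature()` correlates each gene
(on `log2(normalized + 1)`) with the outcome across samples with
non-missing outcome; the positive and negative signatures are the genes
with r > 0 resp. r < 0 at raw p below the threshold (default 0.05). The
p-values are deliberately **unadjusted**: this derivation style screens at
raw thresholds and relies on downstream intersection and stability
selection for control. Ordering is ascending p, ties by descending |r|.
Zero-variance genes are skipped and counted. `excludePlaceboCorrelated()`
removes signature genes that correlate (either sign, default p < 0.05, a
configurable choice since no canonical value exists) with progression in
the placebo arm — progression-rate genes rather than treatment-response
genes. `combineSignatures()` intersects same-direction signatures across
studies, ordering by mean input rank.

**Module scores.** `signatureScore()` is the expression-bin-matched score:
genes are ranked by mean expression and cut into 24 equal-size bins, and
100 control genes per signature gene are drawn (seeded, without
replacement) from the signature gene's bin; the score is mean signature
expression minus mean control expression. The bin/control defaults follow
the widely used single-cell implementation of this score, which names no
parameters in most methods sections; both are arguments, and
`controls = FALSE` gives the plain mean. The signature gene list is sorted
internally before the control draw so the score is invariant to input
order.

## Stability selection

`runStabilityPipeline()` composes, per training partition and per α:

1. **Partitions.** `nPartitions` (default 200) random splits; partition *i*
   is seeded with `masterSeed + i`, so splits are independent but fully
   reproducible. The training set has `round(0.70 · n)` samples. Splits are
   stratified by response via largest-remainder allocation — with small
   cohorts an unstratified split can produce single-class training sets —
   and `stratify = FALSE` restores plain random splits. Sample identifiers
   are sorted before drawing, making the splits invariant to input order.
2. **λ by cross-validation.** For each α in the grid (default 0 to 1 in
   steps of 0.1), `fitEnetCV()` standardizes features (mean 0, sd 1;
   constant features kept as zero columns), builds a 100-value λ path
   log-spaced from the analytic λ_max down to `1e-4 · λ_max`, and picks
   lambda.min by 5-fold stratified CV on mean binomial deviance.
   Coefficients stay on the standardized scale — the scale on which the
   response score and its fixed −0.01 threshold are interpretable.
3. **Bootstrap frequencies.** At the fixed (α, λ_min), `nBootstrap`
   (default 100) resamples with replacement to the original training size;
   a resample that collapses to one class is redrawn (up to 50 attempts)
   rather than skipped, keeping counts out of a constant denominator. Genes
   with non-zero coefficients are counted and their values recorded.
4. **Stable sets and overlap.** The top 33 most frequently selected genes
   (never-selected genes are ineligible; boundary ties broken by larger
   mean |coefficient|, then gene id) form the scenario's stable set. The
   overlap set intersects stable sets across all α > 0 and all partitions
   (`strict` mode, the literal reading); because the source description is
   ambiguous about whether the intersection runs over partitions as well,
   a `fraction` mode (gene stable for every α in ≥ q of partitions,
   default q = 0.5) is also implemented, with the mode recorded in the
   signature's provenance. α = 0 is fitted for path diagnostics but
   excluded from the overlap, as pure ridge never zeroes coefficients and
   performs poorly as a selector.
5. **Median coefficients.** Per overlap gene, the median of all pooled
   non-zero coefficients across bootstraps, α > 0, and partitions; an even
   count averages the central pair.

Why 33 for the stable-set size has no principled derivation; it is kept as
a plain configuration constant.

## Scoring and validation

The response score is `Σ_g coef_g · x_gj` on per-gene standardized
expression (consistent with coefficients learned on standardized features).
`resampledValidation()` draws subsets of 20 samples without replacement
(1,000 by default; single-class subsets are redrawn — a computability
requirement of ROC analysis, not a statistical choice), recording per
subset the rank-formulation AUC (midranks, so ties contribute ½) and the
Youden-J optimal operating point. Youden thresholds are evaluated at
midpoints between consecutive distinct scores plus ±∞, classifying R iff
`score > threshold`; ties on J prefer higher sensitivity, then the lower
threshold. `classifyFixedThreshold()` applies the fixed cut (default
−0.01, i.e. "non-negative score leans responder" under the strict
inequality) and reports FN/FP rates per study and pooled. Responders are
the ROC positive class throughout.

## The synthetic cohort generator

`simulateCohort()` emulates the statistical structure the supervised stages
assume: two studies (defaults: study A with 14 R / 16 NR treated plus 15
untreated controls and two baseline batches; study B with 22 R / 20 NR
treated plus 31 placebo), negative-binomial counts with
`variance = μ + φμ²` (φ = 0.1, a typical bulk RNA-seq dispersion),
log-normal library sizes (log-sd 0.3), per-(gene, batch) multiplicative
log2-normal shifts (sd 0.2), and planted genes shifted ±`effectLog2fc`
between R and NR via a ±½ latent response score. Outcomes are linear in the
latent score plus truncated Gaussian noise — C-peptide
`100 + 60·latent + N(0, 20)` percent of baseline, time to diagnosis
`18 + 12·latent` months with noise scaled by the slope ratio so both share
one signal-to-noise ratio; linearity is the simplest form consistent with
the monotone association the correlation stages assume. Placebo samples
get their own latent progression score (N(0, 0.5²)) expressed on a
dedicated placebo-progression gene set that overlaps the planted set by
50% by default, so the placebo-exclusion filter has genuine work. Planted
gene positions are deterministic in the configuration, letting held-out
cohorts simulated under new seeds share the ground truth.

What it does **not** emulate: gene–gene correlation beyond the planted
effects (real co-expression modules make stability selection's job harder
— correlated proxies can substitute for each other across bootstraps),
cell-type composition shifts (the actual biological driver of whole-blood
signatures), outcome nonlinearity, and missing-data structure. Passing the
planted benchmarks therefore shows the machinery is correct and
well-calibrated, not that real cohorts of this size would yield signatures
of comparable accuracy.

## Benchmark conditions and problem sizes

The planted recovery benchmark uses 10 signal genes among 200, 40 R + 40 NR
samples, |log2 FC| = 2, and a reduced budget of 20 partitions × 2 α × 25
bootstraps; the null-calibration runs use 2,000 genes at zero effect for
the correlation stage and 20 seeded 200-gene cohorts at the 20 × 5 × 25
budget for the strict-overlap null. Benchmark cohorts draw baseline log
means from N(4, 1) — the expressed regime — since signature genes are by
construction expressed genes and the standard filter should not be what
decides recovery. In the strict-overlap null check the running intersection
is computed incrementally and a run stops once it is empty, which is
mathematically identical to intersecting every stable set. These sizes keep
the full suite to a few minutes on one CPU while leaving all assertions at
the stated thresholds.

## Known limitations

- `median-center` aligns batch locations only; batch effects on dispersion
  pass through untouched (use the `external` hook for model-based
  adjustment).
- The exact Wilcoxon path applies only to tie-free genes with both groups
  ≤ 8; normalized expression with many zeros always takes the corrected
  normal approximation.
- Strict-mode overlap becomes increasingly conservative as partitions
  grow; with weak signal it can legitimately be empty (the pipeline then
  warns and returns no signature rather than relaxing the rule silently).
- The generator's independent-gene noise makes selection benchmarks easier
  than real transcriptomes; treat recovery rates as upper bounds.
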