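# stabsig

Stability-selected predictive gene signatures from bulk RNA-seq.

## The problem

Immunotherapies such as anti-CD3 antibody treatment of type 1 diabetes help
only a subset of patients, and reliable pre-treatment biomarkers of response
are scarce. Given bulk whole-blood RNA-seq count matrices from treated
cohorts together with clinical outcomes — C-peptide AUC as a percentage of
baseline, or time to diagnosis — this package derives responder (R) and
nonresponder (NR) gene signatures and builds a compact predictive signature
whose weighted expression sum, the *response score*, separates Rs from NRs.
It is written for computational immunologists and biostatisticians who want
the full procedure as tested, reusable functions rather than a one-off
analysis script.

## The method

Around a standard preprocessing core (median-of-ratios size factors; genes
kept when expressed at least 10 times in at least 40% of samples; a
pluggable batch-adjustment stage), the package implements:

- **Signature derivation.** Two-group Wilcoxon rank-sum differential
  expression with Bonferroni correction and top-k ranking by discriminatory
  power (|standardized W|), and Pearson-correlation signatures against
  continuous outcomes (positive/negative significant genes at a raw p
  threshold), with exclusion of genes that track progression in a placebo
  arm and cross-study intersection of signatures.
- **Stability selection.** The cohort is randomly partitioned many times
  (default 200) into 70% training sets. For each partition and each
  elastic-net mixing value α in {0, 0.1, …, 1}, λ is chosen by 5-fold
  cross-validation at minimum mean binomial deviance (lambda.min); 100
  bootstrap refits at the fixed (α, λ) count how often each gene's
  coefficient is non-zero; the top 33 most frequently selected genes form
  the scenario's stable set. Genes appearing in the stable set across all
  α > 0 and all partitions form the overlap set, and each overlap gene gets
  the median of all its pooled non-zero coefficients.
- **Validation.** The response score `score_j = Σ_g coef_g · x_gj` (on
  per-gene standardized expression) is evaluated by repeated ROC analysis on
  random 20-sample subsets (default 1,000), recording AUC and the
  Youden-J-optimal sensitivity/specificity per subset, plus fixed-threshold
  (default −0.01) classification with per-study false-negative and
  false-positive rates.
- **Synthetic cohorts.** `simulateCohort()` generates two-study
  negative-binomial cohorts with library-size and batch effects, treated and
  placebo/control arms, planted signal genes, and outcomes linearly coupled
  to the latent response — providing ground truth (`truthOverlap()`) for
  every supervised stage.

## Worked example

A down-scaled two-study cohort with 16 planted signal genes among 300, a
moderate planted effect (|log2 FC| = 1), and a reduced selection budget:

```r
library(stabsig)

cfg <- simConfig(
  nGenes = 300, nSignalPos = 8, nSignalNeg = 8, effectLog2fc = 1,
  studies = list(
    AbATE = list(treated = c(R = 14, NR = 16), control = 15, nBatches = 2),
    TN10  = list(treated = c(R = 22, NR = 20), placebo = 31, nBatches = 1)
  ),
  baselineLogMean = c(mean = 4, sd = 1), seed = 42
)
sim <- simulateCohort(cfg)

co  <- normalizeCohort(sim$cohort)
flt <- filterGenes(co)
print(flt$report)
#> gene filter: kept 290 of 300 genes (>= 10 counts in >= 40% of samples)

co <- flt$x
lx <- normalizedValues(co, log2 = TRUE)
cd <- as.data.frame(SummarizedExperiment::colData(co))
treated <- cd$arm == "treated"

scfg <- stabilityConfig(nPartitions = 20, alphaGrid = seq(0.2, 1, 0.2),
                        nBootstrap = 25, topK = 20, masterSeed = 1)
res <- runStabilityPipeline(t(lx[, treated]),
                            responseLabels(co)[treated], scfg)
res$signature
#> PredictiveSignature: 13 genes ( 7 positive / 6 negative coefficients )
truthOverlap(res$overlap, sim$truth)
#>    recall precision
#>    0.8125    1.0000

scores <- responseScore(standardizeExpression(lx[, treated]),
                        res$signature, metadata = cd[treated, ])
resampledValidation(scores, nIterations = 1000, subsetSize = 20, seed = 2)
#> subsampled ROC validation: 1000 x 20 samples
#>   mean AUC 1.000 | mean sensitivity 1.000 | mean specificity 1.000
classifyFixedThreshold(scores, threshold = -0.01)
#>    group TP FN FP TN fn_rate fp_rate
#> 1  AbATE 14  0  0 16       0       0
#> 2   TN10 22  0  0 20       0       0
#> 3 pooled 36  0  0 36       0       0
```

At this budget the pipeline recovers 13 of the 16 planted genes with no
false selections (recall 0.81, precision 1.0); every recovered coefficient
sign matches the planted direction, and the resulting score separates the
simulated cohort cleanly — the planted effect is strong relative to the
negative-binomial noise at n = 72. `runPipeline()` wraps the same stages
end to end with a reproducible run manifest.

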