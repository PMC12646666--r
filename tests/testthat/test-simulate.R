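oneStudy <- function(nR, nNR, ...) {
  simConfig(
    studies = list(S = list(treated = c(R = nR, NR = nNR), nBatches = 1)),
    ...
  )
}

test_that("the simulator is a pure function of its configuration", {
  cfg <- simConfig(nGenes = 100, seed = 42)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(counts(a$cohort), counts(b$cohort))
  expect_identical(
    as.data.frame(SummarizedExperiment::colData(a$cohort)),
    as.data.frame(SummarizedExperiment::colData(b$cohort))
  )
  expect_identical(a$truth, b$truth)

  # a different seed moves the counts
  c2 <- simulateCohort(simConfig(nGenes = 100, seed = 43))
  expect_false(identical(counts(a$cohort), counts(c2$cohort)))
})

test_that("simulated cohorts have the configured structure", {
  cfg <- simConfig(nGenes = 120, nSignalPos = 6, nSignalNeg = 4, seed = 5)
  sim <- simulateCohort(cfg)
  co <- sim$cohort
  cd <- as.data.frame(SummarizedExperiment::colData(co))
  expect_equal(nrow(co), 120L)
  expect_equal(ncol(co), 14 + 16 + 15 + 22 + 20 + 31)
  expect_equal(sum(cd$study == "AbATE" & cd$arm == "control"), 15L)
  expect_equal(sum(cd$study == "TN10" & cd$arm == "placebo"), 31L)
  expect_equal(length(unique(cd$batch[cd$study == "AbATE"])), 2L)
  expect_length(sim$truth$planted_pos, 6L)
  expect_length(sim$truth$planted_neg, 4L)
  expect_length(intersect(sim$truth$planted_pos, sim$truth$planted_neg), 0L)
  # outcomes exist where the design says they should
  expect_true(all(is.na(cd$cpep_auc_pct_baseline_m6[cd$arm == "placebo"])))
  expect_true(all(is.finite(cd$time_to_diagnosis[cd$arm == "placebo"])))
  expect_true(all(cd$time_to_diagnosis >= 0, na.rm = TRUE))
})

test_that("empty response strata are rejected", {
  expect_error(
    simConfig(studies = list(S = list(treated = c(R = 0, NR = 10)))),
    "stratum"
  )
  expect_error(
    simConfig(studies = list(S = list(treated = c(R = 5)))),
    "treated"
  )
})

test_that("empirical per-gene means track the negative-binomial target", {
  # library-size / batch variation off so the target mean is exactly mu_g
  cfg <- oneStudy(250, 250,
    nGenes = 500, nSignalPos = 0, nSignalNeg = 0,
    librarySizeLogSd = 0, batchLogFcSd = 0, dispersion = 0.1, seed = 17,
    placeboProgressionGenes = 0
  )
  sim <- simulateCohort(cfg)
  cm <- counts(sim$cohort)
  set.seed(17) # replay the generator's deterministic mu_g draw
  mu <- exp(rnorm(500, 3, 1.5))
  se <- sqrt((mu + 0.1 * mu^2) / 500)
  frac <- mean(abs(rowMeans(cm) - mu) <= 3 * se)
  expect_gte(frac, 0.99) # ~0.3% of genes may exceed 3 SE by chance
})

test_that("planted genes at strong effect are all Wilcoxon-detectable", {
  cfg <- oneStudy(30, 30,
    nGenes = 300, nSignalPos = 5, nSignalNeg = 5,
    effectLog2fc = 3, dispersion = 0.1, seed = 23,
    placeboProgressionGenes = 0
  )
  sim <- simulateCohort(cfg)
  co <- normalizeCohort(sim$cohort)
  lx <- normalizedValues(co, log2 = TRUE)
  y <- responseLabels(co)
  de <- wilcoxonDE(lx, names(y)[y == "R"], names(y)[y == "NR"])
  planted <- c(sim$truth$planted_pos, sim$truth$planted_neg)
  sub <- de[de$gene_id %in% planted, ]
  expect_equal(nrow(sub), length(planted))
  expect_true(all(sub$adjusted_p < 0.05))
  # planted directions match the sign of the fold change
  expect_true(all(sub$log2_fc[sub$gene_id %in% sim$truth$planted_pos] > 0))
  expect_true(all(sub$log2_fc[sub$gene_id %in% sim$truth$planted_neg] < 0))
})

test_that("placebo progression genes correlate with outcome in placebo only", {
  cfg <- simConfig(
    nGenes = 400, nSignalPos = 10, nSignalNeg = 10,
    studies = list(
      S = list(treated = c(R = 25, NR = 25), placebo = 40, nBatches = 1)
    ),
    effectLog2fc = 2, placeboProgressionGenes = 10, overlapFraction = 0.5,
    seed = 31
  )
  sim <- simulateCohort(cfg)
  co <- normalizeCohort(sim$cohort)
  lx <- normalizedValues(co, log2 = TRUE)
  cd <- as.data.frame(SummarizedExperiment::colData(co))
  placebo <- cd$arm == "placebo"
  ttd <- setNames(cd$time_to_diagnosis, cd$sample_id)
  tabP <- sapply(sim$truth$placebo_progression_genes, function(g) {
    pearsonWithP(lx[g, placebo], ttd[placebo])$p_value
  })
  expect_true(mean(tabP < 0.05) >= 0.8) # strong planted placebo signal
  # half the placebo set overlaps the planted genes by construction
  planted <- c(sim$truth$planted_pos, sim$truth$planted_neg)
  expect_equal(
    sum(sim$truth$placebo_progression_genes %in% planted), 5L
  )
})

test_that("truthOverlap computes recall and precision", {
  truth <- structure(
    list(
      planted_pos = c("a", "b"), planted_neg = c("c", "d"),
      placebo_progression_genes = character(),
      latent_score = numeric()
    ),
    class = "stabsig_ground_truth"
  )
  expect_equal(
    unname(truthOverlap(c("a", "b", "c", "d"), truth)), c(1, 1)
  )
  expect_equal(
    unname(truthOverlap(c("x", "y", "z", "w", "v"), truth)), c(0, 0)
  )
  expect_equal(
    unname(truthOverlap(c("a", "b", "x", "y"), truth)), c(0.5, 0.5)
  )
  empty <- truthOverlap(character(), truth)
  expect_equal(as.numeric(empty), c(0, 1))
  expect_true(attr(empty, "empty_selection"))
})
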