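test_that("pearsonWithP matches hand calculations and the t reference", {
  perf <- pearsonWithP(c(1, 2, 3), c(2, 4, 6))
  expect_equal(perf$r, 1)
  expect_equal(perf$p_value, 0)

  hand <- pearsonWithP(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(hand$r, 0.6)
  # p via t = 0.6 * sqrt(2 / 0.64) on 2 df, from the t CDF directly
  tstat <- 0.6 * sqrt(2 / (1 - 0.36))
  expect_equal(hand$p_value, 2 * pt(-tstat, 2))

  # cross-check against the base correlation test on random data
  set.seed(12)
  for (rep in 1:5) {
    x <- rnorm(15)
    y <- rnorm(15)
    got <- pearsonWithP(x, y)
    ref <- cor.test(x, y)
    expect_equal(got$r, unname(ref$estimate))
    expect_equal(got$p_value, ref$p.value)
  }
})

test_that("pearsonWithP handles missing pairs, degenerate input and affine maps", {
  x <- c(1, 2, NA, 4, 5)
  y <- c(2, 4, 6, NA, 10)
  got <- pearsonWithP(x, y)
  expect_equal(got$n, 3L)
  expect_equal(got$r, 1)

  expect_error(pearsonWithP(1:2, 2:3), ">= 3")
  flat <- pearsonWithP(rep(1, 5), rnorm(5))
  expect_true(is.na(flat$r) && is.na(flat$p_value))

  # r(ax + b, y) = sign(a) * r(x, y)
  set.seed(3)
  x <- rnorm(20)
  y <- rnorm(20)
  r0 <- pearsonWithP(x, y)$r
  expect_equal(pearsonWithP(3 * x + 7, y)$r, r0)
  expect_equal(pearsonWithP(-2 * x + 1, y)$r, -r0)
})

test_that("null p-values are uniform under permutation", {
  set.seed(42)
  x <- rnorm(20)
  y <- rnorm(20)
  ps <- replicate(2000, pearsonWithP(x, sample(y))$p_value)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("correlation signatures split by sign, order by p, stay disjoint", {
  set.seed(8)
  n <- 40
  outcome <- rnorm(n, 100, 20)
  expr <- rbind(
    up1 = outcome + rnorm(n, 0, 5),
    up2 = outcome + rnorm(n, 0, 30),
    down1 = -outcome + rnorm(n, 0, 5),
    noise = rnorm(n)
  )
  colnames(expr) <- paste0("s", 1:n)
  sigs <- pearsonSignature(expr, outcome, pThreshold = 0.05)
  expect_true("up1" %in% geneIds(sigs$positive))
  expect_true("down1" %in% geneIds(sigs$negative))
  expect_length(intersect(geneIds(sigs$positive), geneIds(sigs$negative)), 0L)
  # ordered by ascending p: the tighter gene leads
  expect_identical(geneIds(sigs$positive)[1], "up1")

  # boundary: a zero threshold empties both signatures
  zero <- pearsonSignature(expr, outcome, pThreshold = 0)
  expect_equal(length(zero$positive), 0L)
  expect_equal(length(zero$negative), 0L)

  expect_error(pearsonSignature(expr, rep(1, n)), "constant")
  expect_error(
    pearsonSignature(expr, c(1, 2, rep(NA, n - 2))),
    "fewer than 3"
  )
})

test_that("planted positive genes land in the positive signature", {
  cfg <- simConfig(
    nGenes = 300, nSignalPos = 8, nSignalNeg = 8,
    studies = list(S = list(treated = c(R = 30, NR = 30), nBatches = 1)),
    effectLog2fc = 2, seed = 19, placeboProgressionGenes = 0
  )
  sim <- simulateCohort(cfg)
  co <- normalizeCohort(sim$cohort)
  lx <- normalizedValues(co, log2 = TRUE)
  cd <- as.data.frame(SummarizedExperiment::colData(co))
  out <- setNames(cd$cpep_auc_pct_baseline_m6, cd$sample_id)
  sigs <- pearsonSignature(lx, out, pThreshold = 0.05)
  expect_true(all(sim$truth$planted_pos %in% geneIds(sigs$positive)))
  expect_true(all(sim$truth$planted_neg %in% geneIds(sigs$negative)))
})

test_that("under a permuted outcome the hit count is binomial-null", {
  cfg <- simConfig(
    nGenes = 2000, nSignalPos = 0, nSignalNeg = 0,
    studies = list(S = list(treated = c(R = 30, NR = 30), nBatches = 1)),
    effectLog2fc = 0, seed = 29, placeboProgressionGenes = 0
  )
  sim <- simulateCohort(cfg)
  co <- normalizeCohort(sim$cohort)
  lx <- normalizedValues(co, log2 = TRUE)
  cd <- as.data.frame(SummarizedExperiment::colData(co))
  set.seed(1)
  out <- sample(setNames(cd$cpep_auc_pct_baseline_m6, cd$sample_id))
  names(out) <- cd$sample_id
  sigs <- pearsonSignature(lx, out, pThreshold = 0.05)
  hits <- length(sigs$positive) + length(sigs$negative)
  se <- sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(hits / 2000 - 0.05), 3 * se)
})

test_that("placebo-correlated genes are excluded, survivors keep their order", {
  sig <- GeneSignature(
    name = "base", direction = "positive",
    geneIds = c("g1", "g2", "g3", "g4"),
    statistic = c(0.9, 0.8, 0.7, 0.6),
    pValue = c(1e-4, 1e-3, 1e-2, 2e-2)
  )
  n <- 30
  set.seed(55)
  outcome <- rnorm(n, 18, 4)
  placeboExpr <- rbind(
    g1 = rnorm(n), # independent of outcome -> kept
    g2 = outcome + rnorm(n, 0, 0.5), # tracks progression -> dropped
    g4 = -outcome + rnorm(n, 0, 0.5) # tracks progression -> dropped
  )
  colnames(placeboExpr) <- paste0("p", 1:n)
  out <- excludePlaceboCorrelated(sig, placeboExpr, outcome)
  expect_identical(geneIds(out), c("g1", "g3")) # g3 untestable -> kept
  expect_equal(attr(out, "n_untested"), 1L)

  # no significant placebo correlation: signature unchanged
  quiet <- rbind(g1 = rnorm(n), g2 = rnorm(n), g3 = rnorm(n), g4 = rnorm(n))
  colnames(quiet) <- paste0("p", 1:n)
  expect_identical(geneIds(excludePlaceboCorrelated(sig, quiet, outcome)),
    geneIds(sig))
})

test_that("signature intersection keeps common genes in mean-rank order", {
  mk <- function(ids) {
    GeneSignature("x", "positive",
      geneIds = ids,
      statistic = seq_along(ids)
    )
  }
  a <- mk(c("a", "b", "c"))
  b <- mk(c("b", "c", "d"))
  expect_identical(geneIds(combineSignatures(a, b)), c("b", "c"))
  expect_identical(geneIds(combineSignatures(a, a)), c("a", "b", "c"))
  expect_equal(length(combineSignatures(mk(c("a")), mk(c("z")))), 0L)

  neg <- GeneSignature("y", "negative", geneIds = "a")
  expect_error(combineSignatures(a, neg), "direction mismatch")

  # mean-rank ordering: a gene late in one list but first in the other
  c1 <- mk(c("u", "v", "w"))
  c2 <- mk(c("w", "v", "u"))
  comb <- combineSignatures(c1, c2) # all mean ranks tie at 2 -> lexicographic
  expect_identical(geneIds(comb), c("u", "v", "w"))
})
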