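# shared planted fixture for the selection tests: two informative genes among
# noise, 40 samples
plantedX <- function(n = 40, p = 30, seed = 5) {
  set.seed(seed)
  y <- rep(c("R", "NR"), each = n / 2)
  X <- matrix(rnorm(n * p), n, p,
    dimnames = list(paste0("s", 1:n), sprintf("g%02d", 1:p))
  )
  X[, "g01"] <- X[, "g01"] + ifelse(y == "R", 1.5, -1.5)
  list(X = X, y = setNames(y, rownames(X)))
}

test_that("partitions are stratified, disjoint, exhaustive and reproducible", {
  y <- setNames(rep(c("R", "NR"), each = 5), paste0("s", 1:10))
  cfg <- stabilityConfig(nPartitions = 25, masterSeed = 3)
  parts <- makePartitions(y, cfg)
  for (p in parts) {
    expect_length(p$train, 7L) # round(0.7 * 10)
    expect_length(intersect(p$train, p$test), 0L)
    expect_setequal(c(p$train, p$test), names(y))
    nR <- sum(y[p$train] == "R")
    expect_true(nR %in% c(3L, 4L)) # class proportions within rounding
  }
  # distinct partitions across indices, identical across reruns
  expect_gt(length(unique(vapply(
    parts, function(p) paste(sort(p$train), collapse = ","), ""
  ))), 1L)
  expect_identical(parts, makePartitions(y, cfg))

  expect_error(
    makePartitions(setNames(c("R", rep("NR", 9)), paste0("s", 1:10)), cfg),
    ">= 2"
  )
})

test_that("above the analytic lambda_max every coefficient is zero", {
  px <- plantedX()
  Xs <- scale(px$X)
  y01 <- as.integer(px$y == "R")
  for (alpha in c(0.3, 0.7, 1)) {
    lmax <- lambdaMaxBoundary(Xs, y01, alpha)
    fit <- glmnet::glmnet(Xs, y01,
      family = "binomial", alpha = alpha,
      lambda = c(lmax * 1.0001, lmax * 2), standardize = FALSE
    )
    expect_true(all(as.numeric(coef(fit, s = lmax * 1.0001))[-1] == 0),
      info = paste("alpha", alpha)
    )
  }
})

test_that("cross-validated fits find the separating feature", {
  px <- plantedX()
  fit <- fitEnetCV(px$X, px$y, alpha = 0.5, seed = 11)
  expect_s3_class(fit, "stabsig_enet_fit")
  expect_identical(
    names(which.max(abs(fit$coefficients))), "g01"
  )
  expect_true("g01" %in% fit$selected)
  expect_true(all(diff(fit$cvCurve$lambda) < 0))

  expect_error(fitEnetCV(px$X, px$y, alpha = 1.5), "alpha")
  expect_error(
    fitEnetCV(px$X, setNames(rep("R", 40), rownames(px$X)), alpha = 0.5),
    "both classes"
  )
})

test_that("the returned fit beats a dense grid search of the objective", {
  set.seed(14)
  n <- 8
  X <- matrix(rnorm(n * 2), n, 2,
    dimnames = list(paste0("s", 1:n), c("gA", "gB"))
  )
  y <- setNames(rep(c("R", "NR"), 4), rownames(X))
  # tiny-n fits trip glmnet's small-class advisory warning
  fit <- suppressWarnings(fitEnetCV(X, y, alpha = 0.5, nFolds = 4, seed = 2))
  Xs <- standardizeExpression(t(X))
  Xs <- t(Xs)
  y01 <- as.integer(y == "R")
  objFit <- enetObjective(
    Xs, y01, fit$intercept, fit$coefficients, 0.5, fit$lambda
  )
  grid <- seq(-5, 5, length.out = 41)
  best <- Inf
  for (b1 in grid) {
    for (b2 in grid) {
      o <- optimize(function(b0) {
        enetObjective(Xs, y01, b0, c(b1, b2), 0.5, fit$lambda)
      }, c(-10, 10))$objective
      best <- min(best, o)
    }
  }
  expect_lte(objFit, best + 1e-6)
})

test_that("bootstrap selection counts behave at the boundaries", {
  px <- plantedX()
  zero <- bootstrapSelect(px$X, px$y,
    alpha = 0.5, lambda = 0.05,
    nBootstrap = 0
  )
  expect_true(all(zero$counts == 0))

  bs <- bootstrapSelect(px$X, px$y,
    alpha = 0.5, lambda = 0.03,
    nBootstrap = 20, seed = 9
  )
  expect_equal(unname(bs$counts["g01"]), 20L) # strong feature always selected
  expect_true(all(bs$counts <= 20))
  expect_equal(
    sort(names(bs$coefValues)[lengths(bs$coefValues) > 0]),
    sort(names(bs$counts)[bs$counts > 0])
  )

  # permutation equivariance: shuffling gene columns permutes the counts
  perm <- sample(ncol(px$X))
  bs2 <- bootstrapSelect(px$X[, perm], px$y,
    alpha = 0.5, lambda = 0.03,
    nBootstrap = 20, seed = 9
  )
  expect_identical(bs2$counts[names(bs$counts)], bs$counts)
})

test_that("selection frequency is non-increasing along a lambda ladder", {
  px <- plantedX(seed = 6)
  ladder <- c(0.01, 0.03, 0.09, 0.27)
  tot <- vapply(ladder, function(lam) {
    sum(bootstrapSelect(px$X, px$y,
      alpha = 1, lambda = lam,
      nBootstrap = 15, seed = 13
    )$counts)
  }, numeric(1))
  expect_true(all(diff(tot) <= 0))
})

test_that("top-frequency features apply the tie rules", {
  counts <- c(a = 100L, b = 50L, c = 10L)
  expect_identical(topFrequencyFeatures(counts, 2), c("a", "b"))

  tied <- c(a = 100L, b = 50L, c = 50L)
  mac <- c(a = 1, b = 0.9, c = 0.2)
  expect_identical(topFrequencyFeatures(tied, 2, mac), c("a", "b"))

  few <- c(a = 3L, b = 2L, c = 1L, d = 0L, e = 0L)
  expect_warning(out <- topFrequencyFeatures(few, 33), "only 3")
  expect_identical(out, c("a", "b", "c")) # never-selected genes ineligible
})

test_that("overlap modes implement strict intersection and fraction voting", {
  sets <- list(
    p1 = list(`0.5` = c("a", "b", "x"), `1.0` = c("a", "b")),
    p2 = list(`0.5` = c("a", "b"), `1.0` = c("a", "b", "y")),
    p3 = list(`0.5` = c("a", "c"), `1.0` = c("a", "c"))
  )
  expect_identical(overlapFeatures(sets, "strict"), "a")
  # b: present for both alphas in 2/3 of partitions >= q = 0.5 -> included
  expect_identical(overlapFeatures(sets, "fraction", q = 0.5), c("a", "b"))
  expect_identical(overlapFeatures(sets, "fraction", q = 1), "a")

  same <- list(p1 = list(`1.0` = c("u", "v")), p2 = list(`1.0` = c("u", "v")))
  expect_identical(overlapFeatures(same, "strict"), c("u", "v"))
  expect_identical(overlapFeatures(same, "fraction"), c("u", "v"))

  expect_error(overlapFeatures(list()), "empty")
})

test_that("median coefficients pool values with the even-count convention", {
  vals <- list(
    gA = c(0.2, 0.4, 0.9),
    gB = c(-0.2, -0.4),
    gC = numeric()
  )
  sig <- medianCoefficients(vals, c("gA", "gB"))
  expect_equal(unname(signatureCoefficients(sig)), c(0.4, -0.3))
  expect_error(medianCoefficients(vals, c("gA", "gC")), "no recorded")
  expect_error(medianCoefficients(vals, character()), "empty")
})

test_that("the pipeline is reproducible and equivariant to gene relabeling", {
  px <- plantedX(n = 30, p = 20, seed = 8)
  cfg <- stabilityConfig(
    nPartitions = 3, alphaGrid = c(0.5, 1), nFolds = 3,
    nBootstrap = 8, topK = 5, masterSeed = 17
  )
  r1 <- suppressWarnings(runStabilityPipeline(px$X, px$y, cfg))
  r2 <- suppressWarnings(runStabilityPipeline(px$X, px$y, cfg))
  expect_identical(r1$freqTable, r2$freqTable)
  expect_identical(r1$overlap, r2$overlap)
  if (!is.null(r1$signature)) {
    expect_identical(
      signatureCoefficients(r1$signature),
      signatureCoefficients(r2$signature)
    )
  }

  # sample order must not matter
  perm <- sample(nrow(px$X))
  r3 <- suppressWarnings(
    runStabilityPipeline(px$X[perm, ], px$y[perm], cfg)
  )
  expect_identical(r1$overlap, r3$overlap)

  # gene relabeling g.. -> h.. carries through to the overlap
  X2 <- px$X
  colnames(X2) <- sub("^g", "h", colnames(X2))
  r4 <- suppressWarnings(runStabilityPipeline(X2, px$y, cfg))
  expect_identical(r4$overlap, sub("^g", "h", r1$overlap))
})
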