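# Independent brute-force oracles used across the suite.  These deliberately
# re-derive each quantity with naive loops / full enumeration so that the
# implementation under test is checked against a different route.

# Exact two-sided Wilcoxon rank-sum p by full enumeration of all
# choose(nA + nB, nA) label assignments (doubling rule, capped at 1).
enumWilcoxonP <- function(a, b) {
  nA <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  uOf <- function(idxA) sum(r[idxA]) - nA * (nA + 1) / 2
  uObs <- uOf(seq_len(nA))
  combos <- utils::combn(length(pooled), nA)
  us <- apply(combos, 2L, uOf)
  pLo <- mean(us <= uObs)
  pHi <- mean(us >= uObs)
  min(1, 2 * min(pLo, pHi))
}

# Median-of-ratios size factors with explicit loops.
naiveSizeFactors <- function(counts) {
  m <- ncol(counts)
  geo <- numeric(nrow(counts))
  for (g in seq_len(nrow(counts))) {
    geo[g] <- prod(counts[g, ])^(1 / m)
  }
  s <- numeric(m)
  for (j in seq_len(m)) {
    ratios <- counts[geo > 0, j] / geo[geo > 0]
    s[j] <- median(ratios)
  }
  setNames(s, colnames(counts))
}

# AUC by explicit all-pairs enumeration.
pairsAuc <- function(scores, labels, positive = "R") {
  ps <- scores[labels == positive]
  ns <- scores[labels != positive]
  tot <- 0
  for (p in ps) {
    for (q in ns) {
      tot <- tot + (p > q) + 0.5 * (p == q)
    }
  }
  tot / (length(ps) * length(ns))
}

# Max Youden's J over an exhaustive threshold grid (all observed scores
# shifted slightly, plus +/- Inf), classifying positive iff score > t.
gridYoudenJ <- function(scores, labels, positive = "R") {
  pos <- labels == positive
  grid <- sort(unique(c(-Inf, Inf, scores, scores - 1e-9, scores + 1e-9)))
  best <- -Inf
  for (t in grid) {
    sens <- sum(scores[pos] > t) / sum(pos)
    spec <- sum(scores[!pos] <= t) / sum(!pos)
    best <- max(best, sens + spec - 1)
  }
  best
}

# Elastic-net binomial objective on standardized predictors (glmnet scaling):
# mean negative log-likelihood + lambda * (alpha ||b||_1 + (1-alpha)||b||_2^2/2).
enetObjective <- function(Xs, y01, intercept, beta, alpha, lambda) {
  eta <- as.numeric(intercept + Xs %*% beta)
  ll <- sum(y01 * eta - log1p(exp(eta)))
  -ll / length(y01) +
    lambda * (alpha * sum(abs(beta)) + (1 - alpha) * sum(beta^2) / 2)
}

# Analytic all-zero-coefficients boundary of the lasso/elastic-net path on a
# given predictor matrix (columns as supplied): max_g |<x_g, y - ybar>| / (n a).
lambdaMaxBoundary <- function(Xs, y01, alpha) {
  n <- length(y01)
  max(abs(crossprod(Xs, y01 - mean(y01)))) / (n * alpha)
}

# Small labeled fixture builders ------------------------------------------

randomCounts <- function(nGenes, nSamples, lambda = 30, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(nGenes * nSamples, lambda) + 1L, nGenes, nSamples)
  dimnames(m) <- list(
    sprintf("g%03d", seq_len(nGenes)),
    sprintf("s%03d", seq_len(nSamples))
  )
  storage.mode(m) <- "double"
  m
}

smallMetadata <- function(sampleIds, response = NULL, study = "S",
                          arm = "treated") {
  n <- length(sampleIds)
  data.frame(
    sample_id = sampleIds,
    study = rep_len(study, n),
    arm = rep_len(arm, n),
    response = if (is.null(response)) rep("unknown", n) else response,
    stringsAsFactors = FALSE
  )
}
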