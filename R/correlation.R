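#' @include AllClasses.R
NULL

#' Pearson correlation with a two-sided p-value
#'
#' Computes `r` as the centered cross-product divided by the product of
#' centered norms,
#' with the two-sided p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on
#' `n - 2` degrees of freedom; `|r| = 1` gives `p = 0`.  Pairs with a
#' missing value in either vector are removed first.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `r`, `p_value`, `n` (complete pairs).  If either vector
#'   has zero variance after pair removal, `r` and `p_value` are `NA` (the
#'   signature stage skips such genes).
#' @export
pearsonWithP <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3L) {
    stop("need >= 3 complete pairs")
  }
  xc <- x - mean(x)
  yc <- y - mean(y)
  den <- sqrt(sum(xc^2) * sum(yc^2))
  if (den == 0) {
    return(list(r = NA_real_, p_value = NA_real_, n = n))
  }
  r <- sum(xc * yc) / den
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    return(list(r = r, p_value = 0, n = n))
  }
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p_value = 2 * pt(-abs(tstat), df = n - 2), n = n)
}

# Vectorized per-gene Pearson r and p against one outcome vector.
geneOutcomeCorrelation <- function(expr, outcome) {
  n <- length(outcome)
  r <- suppressWarnings(as.numeric(cor(t(expr), outcome)))
  r <- pmax(-1, pmin(1, r))
  p <- rep(NA_real_, length(r))
  exact <- !is.na(r) & abs(r) == 1
  p[exact] <- 0
  mid <- !is.na(r) & !exact
  tstat <- r[mid] * sqrt((n - 2) / (1 - r[mid]^2))
  p[mid] <- 2 * pt(-abs(tstat), df = n - 2)
  data.frame(
    gene_id = rownames(expr), r = r, p_value = p, n = n,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Correlation-based responder / nonresponder signatures
#'
#' Correlates each gene's expression with a continuous clinical outcome
#' (C-peptide AUC as percentage of baseline, or time to diagnosis) across
#' the samples with a non-missing outcome.  Genes with a positive,
#' significant correlation form the positive (responder) signature; genes
#' with a negative, significant correlation the negative (nonresponder)
#' signature.  P-values are unadjusted, matching the raw significance
#' thresholds this style of signature derivation uses.  Each signature is
#' ordered by ascending p, ties by descending |r|.
#'
#' @param expr genes x samples normalized (typically `log2(x + 1)`)
#'   expression matrix.
#' @param outcome per-sample numeric outcome, aligned with columns of
#'   `expr` (or named by sample).
#' @param pThreshold raw p-value threshold (default 0.05).
#' @param name prefix for the signature names.
#' @return list with [GeneSignature-class] elements `positive` and
#'   `negative`, plus `n_skipped` (zero-variance genes).
#' @export
pearsonSignature <- function(expr, outcome, pThreshold = 0.05, name = "corr") {
  stopifnot(is.matrix(expr))
  if (!is.null(names(outcome))) {
    outcome <- outcome[colnames(expr)]
  }
  stopifnot(length(outcome) == ncol(expr))
  ok <- is.finite(outcome)
  if (sum(ok) < 3L) {
    stop("outcome non-missing for fewer than 3 samples")
  }
  outcome <- outcome[ok]
  expr <- expr[, ok, drop = FALSE]
  if (sd(outcome) == 0) {
    stop("outcome is constant")
  }
  tab <- geneOutcomeCorrelation(expr, outcome)
  nSkipped <- sum(is.na(tab$r))
  tab <- tab[!is.na(tab$r), , drop = FALSE]
  pick <- function(sub, direction) {
    sub <- sub[order(sub$p_value, -abs(sub$r), sub$gene_id), , drop = FALSE]
    GeneSignature(
      name = paste0(name, "_", direction), direction = direction,
      geneIds = sub$gene_id, statistic = sub$r, pValue = sub$p_value
    )
  }
  list(
    positive = pick(
      tab[tab$r > 0 & tab$p_value < pThreshold, , drop = FALSE], "positive"
    ),
    negative = pick(
      tab[tab$r < 0 & tab$p_value < pThreshold, , drop = FALSE], "negative"
    ),
    n_skipped = nSkipped
  )
}

#' Remove genes that track progression in the placebo arm
#'
#' Drops from a signature every gene whose expression correlates (either
#' sign, raw p below `pThreshold`) with the outcome among placebo samples;
#' the order of the survivors is preserved.  Signature genes absent from the
#' placebo matrix are kept (they cannot be tested) and counted in the
#' `"n_untested"` attribute.
#'
#' @param sig a [GeneSignature-class].
#' @param placeboExpr genes x samples expression matrix of the placebo arm.
#' @param placeboOutcome per-sample outcome for the placebo samples.
#' @param pThreshold exclusion threshold (default 0.05).
#' @return the filtered [GeneSignature-class].
#' @export
excludePlaceboCorrelated <- function(sig, placeboExpr, placeboOutcome,
                                     pThreshold = 0.05) {
  stopifnot(is(sig, "GeneSignature"), is.matrix(placeboExpr))
  if (!is.null(names(placeboOutcome))) {
    placeboOutcome <- placeboOutcome[colnames(placeboExpr)]
  }
  ok <- is.finite(placeboOutcome)
  if (sum(ok) < 3L) {
    stop("need >= 3 placebo samples with outcome")
  }
  e <- signatureEntries(sig)
  present <- e$gene_id[e$gene_id %in% rownames(placeboExpr)]
  drop <- character()
  if (length(present)) {
    tab <- geneOutcomeCorrelation(
      placeboExpr[present, ok, drop = FALSE], placeboOutcome[ok]
    )
    drop <- tab$gene_id[!is.na(tab$p_value) & tab$p_value < pThreshold]
  }
  keep <- !(e$gene_id %in% drop)
  out <- GeneSignature(
    name = signatureName(sig), direction = signatureDirection(sig),
    geneIds = e$gene_id[keep], statistic = e$statistic[keep],
    pValue = e$p_value[keep], adjustedP = e$adjusted_p[keep]
  )
  attr(out, "n_untested") <- sum(!e$gene_id %in% rownames(placeboExpr))
  out
}

#' Intersect two same-direction signatures across studies
#'
#' The combined signature is the intersection of the two gene sets, ordered
#' by the mean of the two input ranks (ties broken lexicographically).  The
#' stored statistic is that mean rank; p-values are not carried over.
#'
#' @param sigA,sigB [GeneSignature-class] objects with equal direction.
#' @param name name for the combined signature.
#' @return a [GeneSignature-class].
#' @export
combineSignatures <- function(sigA, sigB, name = NULL) {
  stopifnot(is(sigA, "GeneSignature"), is(sigB, "GeneSignature"))
  if (signatureDirection(sigA) != signatureDirection(sigB)) {
    stop("direction mismatch between signatures")
  }
  if (is.null(name)) {
    name <- paste(signatureName(sigA), signatureName(sigB), sep = " & ")
  }
  gA <- geneIds(sigA)
  gB <- geneIds(sigB)
  common <- intersect(gA, gB)
  meanRank <- (match(common, gA) + match(common, gB)) / 2
  ord <- order(meanRank, common)
  GeneSignature(
    name = name, direction = signatureDirection(sigA),
    geneIds = common[ord], statistic = meanRank[ord]
  )
}
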