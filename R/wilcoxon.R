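#' @include AllClasses.R
NULL

# Rank-sum machinery for a single gene.  U is the Mann-Whitney statistic for
# group A; z is U standardized with the tie-corrected null sd (no continuity
# correction — it is a ranking metric, not a p-value).
rankSumStats <- function(a, b) {
  nA <- length(a)
  nB <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
  N <- nA + nB
  ties <- table(r)
  tieTerm <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- nA * nB / 12 * ((N + 1) - tieTerm)
  z <- if (sigma2 > 0) (U - nA * nB / 2) / sqrt(sigma2) else 0
  hasTies <- any(ties > 1)
  p <- if (nA <= 8 && nB <= 8 && !hasTies) {
    # exact two-sided null enumeration (doubling rule)
    wilcox.test(a, b, exact = TRUE)$p.value
  } else {
    suppressWarnings(
      wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    )
  }
  c(U = U, z = z, p = p)
}

#' Two-group Wilcoxon rank-sum differential expression
#'
#' Marker-style differential expression between two sample groups on a
#' normalized expression matrix.  A gene is tested iff it is detected
#' (value > 0) in at least `minDetectFrac` of group A or of group B, and its
#' absolute log2 fold change passes `logfcThreshold`.  The two-sided p-value
#' uses exact null enumeration when both groups have at most 8 units and the
#' gene's values are tie-free, and the normal approximation with tie and
#' continuity correction otherwise.  Bonferroni adjustment is over the
#' tested genes only.
#'
#' @param expr genes x units normalized expression matrix (cells or
#'   samples).
#' @param groupA,groupB disjoint vectors of column names or indices, each of
#'   size >= 2.
#' @param minDetectFrac detection fraction threshold (default 0.25).
#' @param logfcThreshold minimum |log2 fold change| to test (default 0).
#' @return data.frame with one row per tested gene: `gene_id`, `log2_fc`
#'   (pseudocount 1 on group means), `w_statistic` (Mann-Whitney U for group
#'   A), `z` (standardized W, tie-corrected), `p_value`, `adjusted_p`
#'   (Bonferroni, capped at 1), `pct_detected_A`, `pct_detected_B`.
#' @export
wilcoxonDE <- function(expr, groupA, groupB, minDetectFrac = 0.25,
                       logfcThreshold = 0) {
  stopifnot(is.matrix(expr))
  toIdx <- function(g) {
    if (is.character(g)) match(g, colnames(expr)) else as.integer(g)
  }
  iA <- toIdx(groupA)
  iB <- toIdx(groupB)
  if (anyNA(iA) || anyNA(iB)) {
    stop("unknown sample identifiers in group definition")
  }
  if (length(intersect(iA, iB))) {
    stop("groups overlap")
  }
  if (length(iA) < 2L || length(iB) < 2L) {
    stop("each group needs >= 2 units")
  }
  A <- expr[, iA, drop = FALSE]
  B <- expr[, iB, drop = FALSE]
  pctA <- rowMeans(A > 0)
  pctB <- rowMeans(B > 0)
  meanA <- rowMeans(A)
  meanB <- rowMeans(B)
  log2fc <- log2((meanA + 1) / (meanB + 1))
  tested <- (pctA >= minDetectFrac | pctB >= minDetectFrac) &
    abs(log2fc) >= logfcThreshold
  tested[is.na(tested)] <- FALSE
  idx <- which(tested)
  if (!length(idx)) {
    return(data.frame(
      gene_id = character(), log2_fc = numeric(), w_statistic = numeric(),
      z = numeric(), p_value = numeric(), adjusted_p = numeric(),
      pct_detected_A = numeric(), pct_detected_B = numeric(),
      stringsAsFactors = FALSE
    ))
  }
  st <- vapply(idx, function(g) rankSumStats(A[g, ], B[g, ]), numeric(3L))
  nTested <- length(idx)
  data.frame(
    gene_id = rownames(expr)[idx],
    log2_fc = log2fc[idx],
    w_statistic = st["U", ],
    z = st["z", ],
    p_value = st["p", ],
    adjusted_p = pmin(1, st["p", ] * nTested),
    pct_detected_A = pctA[idx],
    pct_detected_B = pctB[idx],
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Top-k signature from a differential-expression table
#'
#' Keeps genes with Bonferroni-adjusted p at or below `alpha` whose log2
#' fold change matches the requested direction, ranks them by discriminatory
#' power (largest |standardized W|, ties broken by larger |log2 fold
#' change|, then lexicographic gene id), and returns the top `k`.
#'
#' @param de data.frame from [wilcoxonDE()].
#' @param direction `"positive"` (up in group A) or `"negative"`.
#' @param k signature size (default 50).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param name signature name.
#' @return a [GeneSignature-class]; if fewer than `k` genes qualify, all of
#'   them with a warning.
#' @export
topKSignature <- function(de, direction = c("positive", "negative"), k = 50,
                          alpha = 0.05, name = NULL) {
  direction <- match.arg(direction)
  stopifnot(nrow(de) > 0)
  if (k <= 0) {
    stop("k must be positive")
  }
  if (is.null(name)) {
    name <- paste0(direction, "_top", k)
  }
  wantSign <- if (direction == "positive") 1 else -1
  q <- de[de$adjusted_p <= alpha & sign(de$log2_fc) == wantSign, , drop = FALSE]
  ord <- order(-abs(q$z), -abs(q$log2_fc), q$gene_id)
  q <- q[ord, , drop = FALSE]
  if (nrow(q) < k) {
    warning(
      "only ", nrow(q), " genes qualify for a top-", k, " signature"
    )
  }
  q <- head(q, k)
  GeneSignature(
    name = name, direction = direction, geneIds = q$gene_id,
    statistic = q$z, pValue = q$p_value, adjustedP = q$adjusted_p
  )
}
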