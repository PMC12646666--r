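#' @include AllClasses.R
NULL

#' Expression-bin-matched signature score
#'
#' Scores each unit (cell or pseudobulk replicate) for a gene signature as
#' the mean log expression of the signature genes minus the mean of a
#' control gene set drawn from matching average-expression bins: all genes
#' are ranked by mean expression across units and cut into `nBins`
#' equal-size bins; for each signature gene, up to `nCtrl` control genes are
#' sampled (seeded, without replacement) from its bin, and the controls are
#' pooled.  With `controls = FALSE` the plain signature mean is returned.
#'
#' @param expr genes x units log-scale expression matrix (e.g.
#'   `log2(normalized + 1)`).
#' @param sig a [GeneSignature-class].
#' @param nBins number of average-expression bins (default 24).
#' @param nCtrl control genes drawn per signature gene (default 100; capped
#'   at the bin size).
#' @param seed integer seed for the control draw.
#' @param controls set `FALSE` to skip control subtraction.
#' @return data.frame with columns `unit_id`, `signature`, `score` (one row
#'   per unit).  Signature genes absent from `expr` are dropped with a
#'   warning; all absent is an error.
#' @export
signatureScore <- function(expr, sig, nBins = 24, nCtrl = 100, seed = 0L,
                           controls = TRUE) {
  stopifnot(is.matrix(expr), is(sig, "GeneSignature"), nBins >= 1)
  wanted <- geneIds(sig)
  present <- intersect(wanted, rownames(expr))
  if (!length(present)) {
    stop("no signature gene present in the expression matrix")
  }
  if (length(present) < length(wanted)) {
    warning(
      length(wanted) - length(present),
      " signature gene(s) absent from the expression matrix"
    )
  }
  # sorted so the control draw (and hence the score) is invariant to the
  # ordering of the signature genes
  present <- sort(present)
  sigMean <- colMeans(expr[present, , drop = FALSE])
  if (!controls) {
    score <- sigMean
  } else {
    means <- rowMeans(expr)
    rk <- rank(means, ties.method = "first")
    bin <- ceiling(rk * nBins / nrow(expr))
    set.seed(seed)
    ctrl <- unique(unlist(lapply(present, function(g) {
      pool <- rownames(expr)[bin == bin[[match(g, rownames(expr))]]]
      sample(pool, min(nCtrl, length(pool)))
    })))
    score <- sigMean - colMeans(expr[ctrl, , drop = FALSE])
  }
  data.frame(
    unit_id = colnames(expr),
    signature = signatureName(sig),
    score = as.numeric(score),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Pseudobulk aggregation of per-cell expression
#'
#' Collapses single cells into one profile per biological replicate by
#' gene-wise mean.
#'
#' @param expr genes x cells expression matrix.
#' @param replicateLabels per-cell replicate labels (length `ncol(expr)`).
#' @return genes x replicates matrix, replicate columns in first-appearance
#'   order.
#' @export
pseudobulk <- function(expr, replicateLabels) {
  stopifnot(is.matrix(expr), length(replicateLabels) == ncol(expr))
  if (anyNA(replicateLabels)) {
    stop("every cell must carry a replicate label")
  }
  reps <- unique(as.character(replicateLabels))
  out <- vapply(reps, function(r) {
    idx <- which(replicateLabels == r)
    if (!length(idx)) stop("empty replicate: ", r)
    rowMeans(expr[, idx, drop = FALSE])
  }, numeric(nrow(expr)))
  out <- matrix(out, nrow = nrow(expr), dimnames = list(rownames(expr), reps))
  out
}
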