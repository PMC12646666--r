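#' @include AllClasses.R
NULL

#' Per-sample response score
#'
#' The weighted sum of signature-gene expression: `score_j = sum_g coef_g *
#' x[g, j]` over the signature genes present in the matrix.  The expression
#' matrix should be on the scale the coefficients were learned on
#' (standardized per gene; see [standardizeExpression()]).
#'
#' @param expr genes x samples expression matrix.
#' @param sig a [PredictiveSignature-class].
#' @param metadata optional data.frame with `sample_id`, `study`,
#'   `response` columns to join onto the score table.
#' @return data.frame with `sample_id`, `score` (plus `study` / `response`
#'   when metadata is supplied).  Missing signature genes are dropped with a
#'   warning and recorded in the `"missing_genes"` attribute; all missing is
#'   an error.
#' @export
responseScore <- function(expr, sig, metadata = NULL) {
  stopifnot(is.matrix(expr), is(sig, "PredictiveSignature"))
  coefs <- signatureCoefficients(sig)
  present <- intersect(names(coefs), rownames(expr))
  missing <- setdiff(names(coefs), present)
  if (!length(present)) {
    stop("all signature genes are missing from the expression matrix")
  }
  if (length(missing)) {
    warning(
      length(missing), " signature gene(s) missing from the matrix: ",
      paste(head(missing, 5L), collapse = ", ")
    )
  }
  score <- as.numeric(crossprod(
    expr[present, , drop = FALSE],
    coefs[present]
  ))
  out <- data.frame(
    sample_id = colnames(expr), score = score,
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (!is.null(metadata)) {
    md <- as.data.frame(metadata)
    keep <- intersect(c("sample_id", "study", "response"), colnames(md))
    out <- merge(out, md[, keep, drop = FALSE], by = "sample_id", sort = FALSE)
    out <- out[match(colnames(expr), out$sample_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "missing_genes") <- missing
  out
}

#' ROC area under the curve by the rank (Mann-Whitney) formulation
#'
#' `AUC = P(score_R > score_NR) + P(score_R = score_NR) / 2`, computed via
#' midranks; responders are the positive class.
#'
#' @param scores numeric scores.
#' @param labels class labels aligned with `scores`.
#' @param positive label of the positive class (default `"R"`).
#' @return AUC in `[0, 1]`.
#' @export
rocAuc <- function(scores, labels, positive = "R") {
  pos <- labels == positive
  nPos <- sum(pos)
  nNeg <- sum(!pos)
  if (nPos == 0L || nNeg == 0L) {
    stop("both classes must be present")
  }
  r <- rank(scores)
  (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Youden's J optimal classification threshold
#'
#' Evaluates every cut point midway between consecutive distinct sorted
#' scores, plus minus/plus infinity, classifying positive iff
#' `score > threshold`, and returns the threshold maximizing
#' `J = sensitivity + specificity - 1`.  Ties on J are broken by higher
#' sensitivity, then by lower threshold.
#'
#' @inheritParams rocAuc
#' @return list with `threshold`, `sensitivity`, `specificity`, `J`.
#' @export
youdenThreshold <- function(scores, labels, positive = "R") {
  pos <- labels == positive
  nPos <- sum(pos)
  nNeg <- sum(!pos)
  if (nPos == 0L || nNeg == 0L) {
    stop("both classes must be present")
  }
  s <- sort(unique(scores))
  cuts <- c(-Inf, if (length(s) > 1L) (head(s, -1L) + s[-1L]) / 2, Inf)
  sens <- vapply(cuts, function(th) sum(scores[pos] > th) / nPos, numeric(1L))
  spec <- vapply(cuts, function(th) sum(scores[!pos] <= th) / nNeg, numeric(1L))
  J <- sens + spec - 1
  best <- order(-J, -sens, cuts)[1L]
  list(
    threshold = cuts[best], sensitivity = sens[best],
    specificity = spec[best], J = J[best]
  )
}

#' Subsampled ROC validation of a response score
#'
#' Repeatedly draws a subset of the cohort without replacement (redrawn,
#' seeded, when single-class), and per iteration records the ROC AUC and
#' the Youden-optimal threshold with its sensitivity and specificity.
#'
#' @param scoreTable data.frame from [responseScore()] with a `response`
#'   column restricted to `R`/`NR` samples.
#' @param nIterations number of subsets (default 1000).
#' @param subsetSize samples per subset (default 20).
#' @param seed RNG seed.
#' @param positive positive class label (default `"R"`).
#' @return a `stabsig_validation_summary` list: vectors `auc_values`,
#'   `sensitivity_values`, `specificity_values`, `thresholds` (length
#'   `nIterations`) and scalars `mean_auc`, `mean_sensitivity`,
#'   `mean_specificity`.
#' @export
resampledValidation <- function(scoreTable, nIterations = 1000L,
                                subsetSize = 20L, seed = 1L,
                                positive = "R") {
  stopifnot(
    is.data.frame(scoreTable),
    all(c("score", "response") %in% colnames(scoreTable))
  )
  labels <- scoreTable$response
  scores <- scoreTable$score
  n <- length(scores)
  if (n < subsetSize) {
    stop("cohort smaller than the subset size")
  }
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present in the cohort")
  }
  set.seed(seed)
  auc <- sens <- spec <- thr <- numeric(nIterations)
  for (i in seq_len(nIterations)) {
    repeat {
      idx <- sample.int(n, subsetSize)
      if (length(unique(labels[idx])) == 2L) break
    }
    auc[i] <- rocAuc(scores[idx], labels[idx], positive = positive)
    yt <- youdenThreshold(scores[idx], labels[idx], positive = positive)
    sens[i] <- yt$sensitivity
    spec[i] <- yt$specificity
    thr[i] <- yt$threshold
  }
  structure(
    list(
      auc_values = auc, sensitivity_values = sens,
      specificity_values = spec, thresholds = thr,
      mean_auc = mean(auc), mean_sensitivity = mean(sens),
      mean_specificity = mean(spec),
      n_iterations = nIterations, subset_size = subsetSize
    ),
    class = "stabsig_validation_summary"
  )
}

#' @export
print.stabsig_validation_summary <- function(x, ...) {
  cat(sprintf(
    "subsampled ROC validation: %d x %d samples\n  mean AUC %.3f | mean sensitivity %.3f | mean specificity %.3f\n",
    x$n_iterations, x$subset_size, x$mean_auc, x$mean_sensitivity,
    x$mean_specificity
  ))
  invisible(x)
}

#' Fixed-threshold classification of response scores
#'
#' Predicts responder iff `score > threshold` and reports confusion counts
#' and false-negative / false-positive rates per group (e.g. study) and
#' pooled.
#'
#' @param scoreTable data.frame with `score`, `response` and (for grouping)
#'   the `groupBy` column.
#' @param threshold classification threshold (default -0.01).
#' @param groupBy grouping column name (default `"study"`); `NULL` for
#'   pooled only.
#' @param positive positive class label (default `"R"`).
#' @return data.frame with one row per group plus `"pooled"`: `group`,
#'   `TP`, `FN`, `FP`, `TN`, `fn_rate` (= FN / (FN + TP)), `fp_rate`
#'   (= FP / (FP + TN)).
#' @export
classifyFixedThreshold <- function(scoreTable, threshold = -0.01,
                                   groupBy = "study", positive = "R") {
  stopifnot(all(c("score", "response") %in% colnames(scoreTable)))
  tallies <- function(df) {
    predPos <- df$score > threshold
    isPos <- df$response == positive
    TP <- sum(predPos & isPos)
    FN <- sum(!predPos & isPos)
    FP <- sum(predPos & !isPos)
    TN <- sum(!predPos & !isPos)
    data.frame(
      TP = TP, FN = FN, FP = FP, TN = TN,
      fn_rate = if (FN + TP > 0) FN / (FN + TP) else NA_real_,
      fp_rate = if (FP + TN > 0) FP / (FP + TN) else NA_real_
    )
  }
  rows <- list()
  if (!is.null(groupBy) && groupBy %in% colnames(scoreTable)) {
    for (g in unique(scoreTable[[groupBy]])) {
      rows[[g]] <- cbind(
        group = g,
        tallies(scoreTable[scoreTable[[groupBy]] == g, , drop = FALSE])
      )
    }
  }
  rows[["pooled"]] <- cbind(group = "pooled", tallies(scoreTable))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
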