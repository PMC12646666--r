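#' @include AllClasses.R
NULL

#' Median-of-ratios size factors
#'
#' The per-sample scaling constant of the median-of-ratios estimator: for
#' sample j, the median over genes g with a positive geometric mean of
#' `counts[g, j] / geomean_g`.  Only genes with all-positive counts enter
#' the reference (their geometric mean is finite on the log scale).  The
#' median is taken on the ratio scale; with an even reference-gene count the
#' central pair is averaged arithmetically.
#'
#' @param counts genes x samples matrix of non-negative counts.
#' @return list with `raw` (the estimator as stated) and `rescaled` (raw
#'   factors divided by their geometric mean, so they multiply to one), both
#'   named by sample.
#' @examples
#' cm <- matrix(c(1, 4, 4, 16), 2, 2,
#'   dimnames = list(c("g1", "g2"), c("s1", "s2"))
#' )
#' medianOfRatiosSizeFactors(cm)$raw # 0.5, 2
#' @export
medianOfRatiosSizeFactors <- function(counts) {
  stopifnot(is.matrix(counts), is.numeric(counts))
  logc <- log(counts)
  logGeo <- rowMeans(logc)
  use <- is.finite(logGeo)
  if (!any(use)) {
    stop(
      "no gene with all-positive counts; remove all-zero rows or filter ",
      "low-count genes first"
    )
  }
  ratios <- counts[use, , drop = FALSE] / exp(logGeo[use])
  raw <- apply(ratios, 2L, median)
  names(raw) <- colnames(counts)
  list(raw = raw, rescaled = raw / exp(mean(log(raw))))
}

#' Size-factor normalization of a cohort
#'
#' Adds a `normalized` assay (`counts / size factor`, per sample) and stores
#' the raw and geometric-mean-rescaled factors in `colData` columns
#' `sizeFactor` and `sizeFactorRescaled`.  The raw (unrescaled) factors are
#' used for division, matching the median-of-ratios convention.
#'
#' @param cohort a [ResponseCohort-class].
#' @return the cohort with normalization attached.
#' @export
normalizeCohort <- function(cohort) {
  stopifnot(is(cohort, "ResponseCohort"))
  cm <- counts(cohort)
  sf <- medianOfRatiosSizeFactors(cm)
  norm <- sweep(cm, 2L, sf$raw, "/")
  assays(cohort)$normalized <- norm
  colData(cohort)$sizeFactor <- sf$raw
  colData(cohort)$sizeFactorRescaled <- sf$rescaled
  cohort
}

#' Normalized expression values of a cohort
#'
#' @param cohort a cohort processed by [normalizeCohort()].
#' @param log2 if `TRUE`, return `log2(normalized + 1)`, the scale used by
#'   the correlation and scoring stages.
#' @return genes x samples numeric matrix.
#' @export
normalizedValues <- function(cohort, log2 = FALSE) {
  stopifnot(is(cohort, "ResponseCohort"))
  if (!"normalized" %in% assayNames(cohort)) {
    stop("cohort has no 'normalized' assay; run normalizeCohort() first")
  }
  v <- as.matrix(assay(cohort, "normalized"))
  if (log2) base::log2(v + 1) else v
}

#' Filter genes by detection across samples
#'
#' A gene is kept iff it has at least `minCount` counts in at least
#' `minSampleFrac` of the samples (both thresholds inclusive; the fraction
#' comparison is exact, with no rounding of `minSampleFrac * n`).
#'
#' @param x genes x samples count matrix or a [ResponseCohort-class].
#' @param minCount minimum count for a sample to count as expressing
#'   (default 10).
#' @param minSampleFrac minimum fraction of samples expressing (default
#'   0.40).
#' @return list with `x` (the filtered matrix or cohort, gene order
#'   preserved) and `report` (a `stabsig_preprocess_report`:
#'   `n_genes_in`, `n_genes_kept`, thresholds).
#' @export
filterGenes <- function(x, minCount = 10, minSampleFrac = 0.40) {
  stopifnot(minSampleFrac > 0, minSampleFrac <= 1, minCount >= 0)
  cm <- if (is(x, "ResponseCohort")) counts(x) else x
  stopifnot(is.matrix(cm))
  frac <- rowSums(cm >= minCount) / ncol(cm)
  keep <- frac >= minSampleFrac
  report <- list(
    n_genes_in = nrow(cm),
    n_genes_kept = sum(keep),
    min_count = minCount,
    min_sample_frac = minSampleFrac
  )
  class(report) <- "stabsig_preprocess_report"
  out <- if (is(x, "ResponseCohort")) x[keep, ] else cm[keep, , drop = FALSE]
  list(x = out, report = report)
}

#' @export
print.stabsig_preprocess_report <- function(x, ...) {
  cat(sprintf(
    "gene filter: kept %d of %d genes (>= %g counts in >= %g%% of samples)\n",
    x$n_genes_kept, x$n_genes_in, x$min_count, 100 * x$min_sample_frac
  ))
  invisible(x)
}

#' Pluggable batch adjustment of a count matrix
#'
#' The batch-integration stage is a contract, not a fixed algorithm:
#' `"none"` is the identity; `"median-center"` rescales each gene within
#' each batch multiplicatively so batch-wise gene medians match the global
#' gene median (output rounded to the nearest integer and floored at zero);
#' `"external"` passes through a user-supplied adjusted matrix of identical
#' shape (e.g. from an empirical-Bayes batch model run outside the package).
#'
#' @param counts genes x samples count matrix.
#' @param batches per-sample batch labels (named by sample or in column
#'   order).
#' @param method `"none"`, `"median-center"` or `"external"`.
#' @param external adjusted matrix for `method = "external"`.
#' @return adjusted count matrix of identical shape.
#' @export
batchAdjust <- function(counts, batches,
                        method = c("none", "median-center", "external"),
                        external = NULL) {
  method <- match.arg(method)
  stopifnot(is.matrix(counts))
  if (length(batches) != ncol(counts)) {
    stop("need one batch label per sample")
  }
  if (!is.null(names(batches))) {
    if (!setequal(names(batches), colnames(counts))) {
      stop("batch label names do not match sample identifiers")
    }
    batches <- batches[colnames(counts)]
  }
  if (anyNA(batches)) {
    stop("missing batch label")
  }
  if (method == "none") {
    return(counts)
  }
  if (method == "external") {
    if (is.null(external)) {
      stop("method 'external' requires an adjusted matrix")
    }
    if (!identical(dim(external), dim(counts)) ||
      !identical(dimnames(external), dimnames(counts))) {
      stop("external matrix shape or dimnames mismatch")
    }
    msg <- checkCountMatrix(external)
    if (!is.null(msg)) {
      stop("external matrix invalid: ", msg)
    }
    return(external)
  }
  # median-center
  tab <- table(batches)
  if (any(tab < 2L)) {
    stop("median-center requires >= 2 samples per batch")
  }
  out <- counts
  globalMed <- apply(counts, 1L, median)
  for (b in unique(batches)) {
    idx <- which(batches == b)
    batchMed <- apply(counts[, idx, drop = FALSE], 1L, median)
    fac <- ifelse(batchMed > 0, globalMed / batchMed, 1)
    out[, idx] <- counts[, idx, drop = FALSE] * fac
  }
  out <- round(out)
  out[out < 0] <- 0
  out
}
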