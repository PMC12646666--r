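#' @include stabsig-package.R
NULL

ARM_LEVELS <- c("treated", "placebo", "control")
RESPONSE_LEVELS <- c("R", "NR", "unknown")
DIRECTION_LEVELS <- c("positive", "negative")

# -- internal validation of a raw count matrix -------------------------------

# Returns NULL when valid, otherwise a character message naming the first
# offending cell by gene/sample identifier.
checkCountMatrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    return("counts must be a numeric matrix")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    return("counts must carry gene (row) and sample (column) identifiers")
  }
  if (anyDuplicated(rownames(counts))) {
    return(sprintf(
      "duplicate gene identifier: '%s'",
      rownames(counts)[duplicated(rownames(counts))][1L]
    ))
  }
  if (anyDuplicated(colnames(counts))) {
    return(sprintf(
      "duplicate sample identifier: '%s'",
      colnames(counts)[duplicated(colnames(counts))][1L]
    ))
  }
  bad <- !is.finite(counts) | counts < 0 | abs(counts - round(counts)) > 1e-8
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    return(sprintf(
      "invalid count (negative, non-finite or non-integer) at gene '%s', sample '%s': %s",
      rownames(counts)[idx[1L]], colnames(counts)[idx[2L]],
      format(counts[idx[1L], idx[2L]])
    ))
  }
  NULL
}

# == ResponseCohort ==========================================================

#' ResponseCohort: counts plus clinical metadata
#'
#' An S4 container extending [SummarizedExperiment::SummarizedExperiment]
#' holding a genes x samples integer count matrix (assay `"counts"`) and
#' per-sample clinical metadata in `colData`: `study`, `arm`
#' (treated/placebo/control), `response` (R/NR/unknown), the continuous
#' outcomes `cpep_auc_pct_baseline_m6`, `cpep_auc_pct_baseline_m12` and
#' `time_to_diagnosis`, plus `batch`, `age`, `sex` where available.
#'
#' @slot ... inherited from SummarizedExperiment.
#' @export
setClass("ResponseCohort", contains = "SummarizedExperiment")

setValidity("ResponseCohort", function(object) {
  if (!"counts" %in% assayNames(object)) {
    return("assay 'counts' is required")
  }
  msg <- checkCountMatrix(as.matrix(assay(object, "counts")))
  if (!is.null(msg)) {
    return(msg)
  }
  cd <- colData(object)
  need <- c("study", "arm", "response")
  miss <- setdiff(need, colnames(cd))
  if (length(miss)) {
    return(paste0("missing metadata column(s): ", paste(miss, collapse = ", ")))
  }
  if (!all(as.character(cd$arm) %in% ARM_LEVELS)) {
    return(paste0("arm must be one of: ", paste(ARM_LEVELS, collapse = ", ")))
  }
  if (!all(as.character(cd$response) %in% RESPONSE_LEVELS)) {
    return(paste0(
      "response must be one of: ",
      paste(RESPONSE_LEVELS, collapse = ", ")
    ))
  }
  TRUE
})

#' Construct a ResponseCohort from counts and sample metadata
#'
#' @param counts genes x samples matrix of non-negative integers with gene
#'   row names and sample column names.
#' @param metadata data.frame with one row per sample; must contain
#'   `sample_id`, `study` and `arm`, and may carry `response`, outcome,
#'   `batch`, `age` and `sex` columns.  Rows are matched to count columns by
#'   exact `sample_id` string.
#' @return a validated [ResponseCohort-class] object.
#' @examples
#' cm <- matrix(0:3, 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' md <- data.frame(
#'   sample_id = c("s1", "s2"), study = "A",
#'   arm = "treated", response = c("R", "NR")
#' )
#' ResponseCohort(cm, md)
#' @export
ResponseCohort <- function(counts, metadata) {
  msg <- checkCountMatrix(counts)
  if (!is.null(msg)) {
    stop(msg)
  }
  if (!is.data.frame(metadata) && !is(metadata, "DataFrame")) {
    stop("metadata must be a data.frame")
  }
  metadata <- as.data.frame(metadata)
  if (!"sample_id" %in% colnames(metadata)) {
    stop("metadata must contain a 'sample_id' column")
  }
  if (anyDuplicated(metadata$sample_id)) {
    stop(
      "duplicate sample_id in metadata: '",
      metadata$sample_id[duplicated(metadata$sample_id)][1L], "'"
    )
  }
  miss <- setdiff(colnames(counts), metadata$sample_id)
  if (length(miss)) {
    stop("samples without metadata: ", paste(head(miss, 5L), collapse = ", "))
  }
  metadata <- metadata[match(colnames(counts), metadata$sample_id), , drop = FALSE]
  if (!"response" %in% colnames(metadata)) {
    metadata$response <- "unknown"
  }
  metadata$response[is.na(metadata$response) | metadata$response == ""] <- "unknown"
  cd <- DataFrame(metadata, row.names = metadata$sample_id)
  new(
    "ResponseCohort",
    SummarizedExperiment(
      assays = list(counts = counts),
      colData = cd
    )
  )
}

#' @describeIn ResponseCohort raw counts accessor.
#' @param object a ResponseCohort.
#' @export
setMethod("counts", "ResponseCohort", function(object) {
  as.matrix(assay(object, "counts"))
})

#' Response labels of a cohort
#'
#' @param object a [ResponseCohort-class].
#' @return character vector named by sample, values in `R`, `NR`, `unknown`.
#' @export
responseLabels <- function(object) {
  stopifnot(is(object, "ResponseCohort"))
  setNames(as.character(colData(object)$response), colnames(object))
}

setMethod("show", "ResponseCohort", function(object) {
  cd <- colData(object)
  cat(
    "ResponseCohort:", nrow(object), "genes x", ncol(object), "samples\n",
    "studies:", paste(unique(as.character(cd$study)), collapse = ", "), "\n",
    "arms:   ", paste(names(table(as.character(cd$arm))),
      table(as.character(cd$arm)),
      sep = "=", collapse = ", "
    ), "\n",
    "response:", paste(names(table(as.character(cd$response))),
      table(as.character(cd$response)),
      sep = "=", collapse = ", "
    ), "\n"
  )
  invisible(NULL)
})

# == GeneSignature ===========================================================

#' GeneSignature: an ordered, directed gene set
#'
#' Holds the genes of a responder or nonresponder signature in rank order
#' together with a per-gene statistic (standardized Wilcoxon W for
#' differential-expression signatures, Pearson r for correlation signatures),
#' the raw p-value, and the Bonferroni-adjusted p-value where applicable.
#'
#' @slot name character signature name.
#' @slot direction `"positive"` or `"negative"`.
#' @slot entries data.frame with columns `gene_id`, `statistic`, `p_value`,
#'   `adjusted_p`, ordered by the deriving procedure's ranking.
#' @export
setClass("GeneSignature",
  representation(
    name = "character",
    direction = "character",
    entries = "data.frame"
  )
)

setValidity("GeneSignature", function(object) {
  if (length(object@direction) != 1L ||
    !object@direction %in% DIRECTION_LEVELS) {
    return(paste0(
      "direction must be one of: ",
      paste(DIRECTION_LEVELS, collapse = ", ")
    ))
  }
  need <- c("gene_id", "statistic", "p_value", "adjusted_p")
  if (!all(need %in% colnames(object@entries))) {
    return(paste0("entries must have columns: ", paste(need, collapse = ", ")))
  }
  e <- object@entries
  if (anyDuplicated(e$gene_id)) {
    return("duplicate gene_id within signature")
  }
  pOk <- function(p) all(is.na(p) | (p >= 0 & p <= 1))
  if (!pOk(e$p_value) || !pOk(e$adjusted_p)) {
    return("p-values must lie in [0, 1]")
  }
  TRUE
})

#' Construct a GeneSignature
#'
#' @param name signature name.
#' @param direction `"positive"` or `"negative"`.
#' @param geneIds character vector of gene identifiers, in rank order.
#' @param statistic per-gene statistic (same length as `geneIds`).
#' @param pValue raw p-values.
#' @param adjustedP adjusted p-values (`NA` when not applicable).
#' @return a [GeneSignature-class].
#' @export
GeneSignature <- function(name, direction, geneIds = character(),
                          statistic = rep(NA_real_, length(geneIds)),
                          pValue = rep(NA_real_, length(geneIds)),
                          adjustedP = rep(NA_real_, length(geneIds))) {
  entries <- data.frame(
    gene_id = as.character(geneIds),
    statistic = as.numeric(statistic),
    p_value = as.numeric(pValue),
    adjusted_p = as.numeric(adjustedP),
    stringsAsFactors = FALSE
  )
  rownames(entries) <- NULL
  new("GeneSignature",
    name = as.character(name),
    direction = as.character(direction), entries = entries
  )
}

#' Gene identifiers of a signature
#'
#' @param object a [GeneSignature-class] or [PredictiveSignature-class].
#' @return character vector in rank order.
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' @rdname geneIds
#' @export
setMethod("geneIds", "GeneSignature", function(object) {
  object@entries$gene_id
})

#' Signature entries table
#'
#' @param object a [GeneSignature-class].
#' @return data.frame of gene_id / statistic / p_value / adjusted_p rows in
#'   rank order.
#' @export
signatureEntries <- function(object) {
  stopifnot(is(object, "GeneSignature"))
  object@entries
}

#' Direction of a signature
#' @param object a [GeneSignature-class].
#' @return `"positive"` or `"negative"`.
#' @export
signatureDirection <- function(object) {
  stopifnot(is(object, "GeneSignature"))
  object@direction
}

#' Name of a signature
#' @param object a [GeneSignature-class].
#' @return character scalar.
#' @export
signatureName <- function(object) {
  stopifnot(is(object, "GeneSignature"))
  object@name
}

setMethod("length", "GeneSignature", function(x) nrow(x@entries))

setMethod("show", "GeneSignature", function(object) {
  cat(
    "GeneSignature '", object@name, "' (", object@direction, "): ",
    nrow(object@entries), " genes\n",
    sep = ""
  )
  if (nrow(object@entries)) {
    cat(
      " top:",
      paste(head(object@entries$gene_id, 5L), collapse = ", "), "\n"
    )
  }
  invisible(NULL)
})

# == PredictiveSignature =====================================================

#' PredictiveSignature: genes with median elastic-net coefficients
#'
#' The output of the stability-selection pipeline: the cross-alpha overlap
#' gene set with, per gene, the median of all non-zero coefficient values
#' pooled across bootstrap iterations, alpha values and training partitions.
#' The induced per-sample response score is the coefficient-weighted sum of
#' (standardized) expression.
#'
#' @slot entries data.frame with columns `gene_id`, `median_coefficient`
#'   (never zero or `NA`).
#' @slot provenance list describing the configuration that produced it.
#' @export
setClass("PredictiveSignature",
  representation(entries = "data.frame", provenance = "list")
)

setValidity("PredictiveSignature", function(object) {
  need <- c("gene_id", "median_coefficient")
  if (!all(need %in% colnames(object@entries))) {
    return(paste0("entries must have columns: ", paste(need, collapse = ", ")))
  }
  e <- object@entries
  if (anyDuplicated(e$gene_id)) {
    return("duplicate gene_id")
  }
  if (any(!is.finite(e$median_coefficient)) ||
    any(e$median_coefficient == 0)) {
    return("median coefficients must be finite and non-zero")
  }
  TRUE
})

#' Construct a PredictiveSignature
#'
#' @param geneIds character vector of gene identifiers.
#' @param coefficients per-gene median coefficients (finite, non-zero).
#' @param provenance optional list recording how the signature was produced.
#' @return a [PredictiveSignature-class].
#' @export
PredictiveSignature <- function(geneIds, coefficients, provenance = list()) {
  entries <- data.frame(
    gene_id = as.character(geneIds),
    median_coefficient = as.numeric(coefficients),
    stringsAsFactors = FALSE
  )
  rownames(entries) <- NULL
  new("PredictiveSignature", entries = entries, provenance = provenance)
}

#' @describeIn PredictiveSignature gene identifiers.
#' @param object a PredictiveSignature.
#' @export
setMethod("geneIds", "PredictiveSignature", function(object) {
  object@entries$gene_id
})

#' Median coefficients of a predictive signature
#'
#' @param object a [PredictiveSignature-class].
#' @return named numeric vector of median coefficients.
#' @export
signatureCoefficients <- function(object) {
  stopifnot(is(object, "PredictiveSignature"))
  setNames(object@entries$median_coefficient, object@entries$gene_id)
}

setMethod("length", "PredictiveSignature", function(x) nrow(x@entries))

setMethod("show", "PredictiveSignature", function(object) {
  e <- object@entries
  cat(
    "PredictiveSignature:", nrow(e), "genes (",
    sum(e$median_coefficient > 0), "positive /",
    sum(e$median_coefficient < 0), "negative coefficients )\n"
  )
  invisible(NULL)
})
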