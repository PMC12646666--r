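#' @include AllClasses.R
NULL

# All tabular formats are tab-delimited UTF-8 with '.' decimal; genes are
# rows and samples are columns everywhere.

#' Read a gene x sample count matrix
#'
#' Two dialects are supported: a TSV with a header row of sample identifiers
#' and gene identifiers in the first column, and MatrixMarket coordinate
#' format with sidecar one-identifier-per-line gene and sample files.
#'
#' @param path path to the TSV or `.mtx` file.
#' @param format `"tsv"` or `"mtx"`.
#' @param geneFile,sampleFile sidecar identifier files for `format = "mtx"`;
#'   default `<path>.genes` / `<path>.samples`.
#' @return validated genes x samples integer matrix with dimnames.  Negative,
#'   non-finite or fractional cells are rejected with the offending gene and
#'   sample named in the error.
#' @export
readCountMatrix <- function(path, format = c("tsv", "mtx"),
                            geneFile = paste0(path, ".genes"),
                            sampleFile = paste0(path, ".samples")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  if (format == "tsv") {
    df <- read.delim(path,
      header = TRUE, sep = "\t", check.names = FALSE,
      stringsAsFactors = FALSE
    )
    if (ncol(df) < 2L) {
      stop("count TSV must have a gene-id column plus sample columns")
    }
    ids <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
  } else {
    if (!file.exists(geneFile) || !file.exists(sampleFile)) {
      stop("sidecar identifier files not found: ", geneFile, ", ", sampleFile)
    }
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(geneFile)
    colnames(m) <- readLines(sampleFile)
  }
  msg <- checkCountMatrix(m)
  if (!is.null(msg)) {
    stop(msg)
  }
  m
}

#' Write a count matrix
#'
#' @param counts genes x samples integer matrix with dimnames.
#' @param path output path.
#' @param format `"tsv"` or `"mtx"` (the latter writes sidecar `.genes` /
#'   `.samples` identifier files next to the `.mtx`).
#' @return `path`, invisibly.
#' @export
writeCountMatrix <- function(counts, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  msg <- checkCountMatrix(counts)
  if (!is.null(msg)) {
    stop(msg)
  }
  if (format == "tsv") {
    df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
    write.table(df, path,
      sep = "\t", quote = FALSE, row.names = FALSE,
      fileEncoding = "UTF-8"
    )
  } else {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    writeLines(rownames(counts), paste0(path, ".genes"))
    writeLines(colnames(counts), paste0(path, ".samples"))
  }
  invisible(path)
}

#' Read per-sample clinical metadata
#'
#' Expects a TSV with header; `sample_id`, `study` and `arm` are required.
#' Recognised outcome/covariate columns (`cpep_auc_pct_baseline_m6`,
#' `cpep_auc_pct_baseline_m12`, `time_to_diagnosis`, `age`) are coerced to
#' numeric; cells that fail to parse become missing and are counted in a
#' single warning (the count is also attached as attribute
#' `"n_parse_failures"`).  Empty or `NA` response cells become `"unknown"`.
#'
#' @param path path to metadata TSV.
#' @return data.frame with one typed row per sample.
#' @export
readSampleMetadata <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  df <- read.delim(path,
    header = TRUE, sep = "\t", check.names = FALSE,
    stringsAsFactors = FALSE, colClasses = "character",
    na.strings = c("NA", "")
  )
  need <- c("sample_id", "study", "arm")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) {
    stop(
      "duplicate sample_id: '",
      df$sample_id[duplicated(df$sample_id)][1L], "'"
    )
  }
  bad <- setdiff(unique(df$arm), ARM_LEVELS)
  if (length(bad)) {
    stop("unknown arm value(s): ", paste(bad, collapse = ", "))
  }
  numericCols <- intersect(
    c(
      "cpep_auc_pct_baseline_m6", "cpep_auc_pct_baseline_m12",
      "time_to_diagnosis", "age"
    ),
    colnames(df)
  )
  nFail <- 0L
  for (cc in numericCols) {
    raw <- df[[cc]]
    num <- suppressWarnings(as.numeric(raw))
    nFail <- nFail + sum(!is.na(raw) & is.na(num))
    df[[cc]] <- num
  }
  if (nFail > 0L) {
    warning(nFail, " unparseable outcome value(s) set to missing")
  }
  if ("response" %in% colnames(df)) {
    df$response[is.na(df$response)] <- "unknown"
    bad <- setdiff(unique(df$response), RESPONSE_LEVELS)
    if (length(bad)) {
      stop("unknown response value(s): ", paste(bad, collapse = ", "))
    }
  } else {
    df$response <- "unknown"
  }
  attr(df, "n_parse_failures") <- nFail
  df
}

#' Write per-sample clinical metadata
#'
#' @param metadata data.frame with a `sample_id` column.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeSampleMetadata <- function(metadata, path) {
  write.table(as.data.frame(metadata), path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, fileEncoding = "UTF-8", na = "NA"
  )
  invisible(path)
}

#' Write a gene signature to TSV
#'
#' Columns: `name`, `direction`, `gene_id`, `rank`, `statistic`, `p_value`,
#' `adjusted_p`.  The round trip through [readGeneSignature()] is lossless
#' for non-empty signatures; an empty signature writes a header-only file.
#'
#' @param sig a [GeneSignature-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneSignature <- function(sig, path) {
  stopifnot(is(sig, "GeneSignature"))
  e <- signatureEntries(sig)
  df <- data.frame(
    name = rep(signatureName(sig), nrow(e)),
    direction = rep(signatureDirection(sig), nrow(e)),
    gene_id = e$gene_id,
    rank = seq_len(nrow(e)),
    statistic = e$statistic,
    p_value = e$p_value,
    adjusted_p = e$adjusted_p,
    stringsAsFactors = FALSE
  )
  write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    fileEncoding = "UTF-8", na = "NA"
  )
  invisible(path)
}

#' Read a gene signature from TSV
#'
#' @param path path written by [writeGeneSignature()].
#' @return a [GeneSignature-class]; a header-only file yields an empty
#'   signature.  A `direction` outside positive/negative is an error.
#' @export
readGeneSignature <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  df <- read.delim(path,
    header = TRUE, sep = "\t", check.names = FALSE,
    stringsAsFactors = FALSE, na.strings = "NA"
  )
  need <- c(
    "name", "direction", "gene_id", "rank", "statistic", "p_value",
    "adjusted_p"
  )
  miss <- setdiff(need, colnames(df))
  if (length(miss)) {
    stop("missing signature column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    return(GeneSignature(name = "", direction = "positive"))
  }
  dirs <- unique(df$direction)
  if (length(dirs) != 1L || !dirs %in% DIRECTION_LEVELS) {
    stop(
      "direction must be a single value in {positive, negative}; got: ",
      paste(dirs, collapse = ", ")
    )
  }
  df <- df[order(df$rank), , drop = FALSE]
  GeneSignature(
    name = df$name[1L], direction = dirs,
    geneIds = df$gene_id, statistic = df$statistic,
    pValue = df$p_value, adjustedP = df$adjusted_p
  )
}

#' Write a predictive signature to TSV
#'
#' Columns: `gene_id`, `median_coefficient`.
#'
#' @param sig a [PredictiveSignature-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePredictiveSignature <- function(sig, path) {
  stopifnot(is(sig, "PredictiveSignature"))
  write.table(sig@entries, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' Read a predictive signature from TSV
#'
#' @param path path written by [writePredictiveSignature()].
#' @return a [PredictiveSignature-class].
#' @export
readPredictiveSignature <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  PredictiveSignature(df$gene_id, df$median_coefficient)
}
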