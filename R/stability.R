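#' @include AllClasses.R
NULL

#' Configuration of the stability-selection pipeline
#'
#' Defaults follow the full procedure: 200 random 70/30 partitions, the
#' alpha grid from 0 (ridge) to 1 (lasso) in steps of 0.1, 5-fold
#' cross-validated lambda at minimum mean binomial deviance, 100 bootstrap
#' iterations per (partition, alpha), top-33 stable sets, and a strict
#' cross-alpha overlap that excludes alpha = 0.  All budget parameters scale
#' down for testing.
#'
#' @param nPartitions number of random train/test partitions (default 200).
#' @param trainFrac training fraction (default 0.70).
#' @param alphaGrid elastic-net mixing values in `[0, 1]`.
#' @param nFolds cross-validation folds for lambda (default 5).
#' @param nBootstrap bootstrap iterations per scenario (default 100).
#' @param topK stable-set size per scenario (default 33).
#' @param masterSeed master seed; partition i uses seed `masterSeed + i`,
#'   and CV/bootstrap seeds are derived deterministically.
#' @param overlapMode `"strict"` (intersection over every scenario) or
#'   `"fraction"` (gene in the stable set for every alpha in at least
#'   `overlapQ` of partitions).
#' @param overlapQ partition fraction for `"fraction"` mode (default 0.5).
#' @param stratify stratify partitions by response (default `TRUE`); set
#'   `FALSE` for plain random splits.
#' @param nLambda,lambdaMinRatio lambda path: `nLambda` values log-spaced
#'   from lambda_max down to `lambdaMinRatio * lambda_max`.
#' @return a `stabsig_stability_config` list.
#' @export
stabilityConfig <- function(nPartitions = 200L, trainFrac = 0.70,
                            alphaGrid = seq(0, 1, by = 0.1),
                            nFolds = 5L, nBootstrap = 100L, topK = 33L,
                            masterSeed = 1L,
                            overlapMode = c("strict", "fraction"),
                            overlapQ = 0.5, stratify = TRUE,
                            nLambda = 100L, lambdaMinRatio = 1e-4) {
  overlapMode <- match.arg(overlapMode)
  cfg <- list(
    nPartitions = as.integer(nPartitions), trainFrac = trainFrac,
    alphaGrid = as.numeric(alphaGrid),
    alphasForOverlap = setdiff(as.numeric(alphaGrid), 0),
    nFolds = as.integer(nFolds), nBootstrap = as.integer(nBootstrap),
    topK = as.integer(topK), masterSeed = as.integer(masterSeed),
    overlapMode = overlapMode, overlapQ = overlapQ,
    stratify = isTRUE(stratify),
    nLambda = as.integer(nLambda), lambdaMinRatio = lambdaMinRatio
  )
  stopifnot(
    cfg$nPartitions >= 1L, cfg$trainFrac > 0, cfg$trainFrac < 1,
    all(cfg$alphaGrid >= 0 & cfg$alphaGrid <= 1),
    length(cfg$alphasForOverlap) >= 1L,
    cfg$nFolds >= 2L, cfg$nBootstrap >= 0L, cfg$topK >= 1L,
    cfg$overlapQ > 0, cfg$overlapQ <= 1
  )
  class(cfg) <- "stabsig_stability_config"
  cfg
}

# Binary response vector (named, values "R"/"NR") from assorted inputs.
asResponseVector <- function(y) {
  y <- as.character(y)
  bad <- setdiff(unique(y), c("R", "NR"))
  if (length(bad)) {
    stop(
      "response labels must be 'R'/'NR' for supervised stages; got: ",
      paste(bad, collapse = ", ")
    )
  }
  y
}

#' Random stratified train/test partitions
#'
#' Draws `nPartitions` splits; partition i uses seed `masterSeed + i`.  The
#' training set has `round(trainFrac * n)` samples, allocated over the
#' response classes by largest remainder so the train class proportions
#' match the cohort within rounding (unless `stratify = FALSE`).
#'
#' @param y named vector of response labels (`"R"`/`"NR"`), one per sample.
#' @param cfg a [stabilityConfig()].
#' @return list of `list(train =, test =)` character vectors of sample
#'   names.
#' @export
makePartitions <- function(y, cfg) {
  labels <- asResponseVector(y)
  ids <- names(y)
  if (is.null(ids)) {
    stop("y must be named by sample")
  }
  # canonical identifier order makes the splits invariant to input order
  ord <- order(ids)
  ids <- ids[ord]
  labels <- labels[ord]
  n <- length(y)
  nTrain <- round(cfg$trainFrac * n)
  classes <- sort(unique(labels))
  if (any(table(labels) < 2L)) {
    stop("each response class needs >= 2 samples")
  }
  lapply(seq_len(cfg$nPartitions), function(i) {
    set.seed(cfg$masterSeed + i)
    if (cfg$stratify) {
      target <- cfg$trainFrac * table(labels)[classes]
      base <- floor(target)
      rem <- nTrain - sum(base)
      if (rem > 0) {
        extra <- order(-(target - base), classes)[seq_len(rem)]
        base[extra] <- base[extra] + 1L
      }
      train <- unlist(lapply(classes, function(cl) {
        sample(ids[labels == cl], base[[cl]])
      }), use.names = FALSE)
    } else {
      train <- sample(ids, nTrain)
    }
    list(train = train, test = setdiff(ids, train))
  })
}

# Stratified CV fold assignment; caller seeds the RNG.
makeFoldIds <- function(y01, nFolds) {
  fid <- integer(length(y01))
  for (cl in unique(y01)) {
    idx <- sample(which(y01 == cl))
    fid[idx] <- rep_len(seq_len(nFolds), length(idx))
  }
  fid
}

#' Elastic-net logistic fit with cross-validated lambda
#'
#' Fits the penalized binomial objective
#' `-(1/n) sum(loglik) + lambda * (alpha ||b||_1 + (1 - alpha) ||b||_2^2 / 2)`
#' over a descending lambda path (`nLambda` values, log-spaced from
#' lambda_max to `lambdaMinRatio * lambda_max`) and selects lambda_min, the
#' value minimizing mean held-out binomial deviance over stratified folds.
#' Features are standardized to mean 0, sd 1 before fitting (constant
#' features kept as zero columns) and coefficients are reported on that
#' standardized scale.
#'
#' @param X samples x genes numeric matrix.
#' @param y response labels (`"R"`/`"NR"`); `"R"` is the positive class.
#' @param alpha elastic-net mixing parameter in `[0, 1]`.
#' @param nFolds CV folds (default 5).
#' @param seed RNG seed for the fold assignment.
#' @param nLambda,lambdaMinRatio lambda path settings.
#' @return a `stabsig_enet_fit` list: `alpha`, `lambda` (lambda_min),
#'   `intercept`, `coefficients` (named, standardized scale), `selected`
#'   (non-zero genes), `cvCurve` (`lambda`, `deviance`).
#' @export
fitEnetCV <- function(X, y, alpha, nFolds = 5L, seed = 1L,
                      nLambda = 100L, lambdaMinRatio = 1e-4) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (alpha < 0 || alpha > 1) {
    stop("alpha must lie in [0, 1]")
  }
  y01 <- as.integer(asResponseVector(y) == "R")
  if (length(unique(y01)) < 2L) {
    stop("both classes must be present")
  }
  Xs <- standardizeColumns(X)
  set.seed(seed)
  foldid <- makeFoldIds(y01, nFolds)
  cv <- glmnet::cv.glmnet(Xs, y01,
    family = "binomial", alpha = alpha,
    foldid = foldid, standardize = FALSE, type.measure = "deviance",
    nlambda = nLambda, lambda.min.ratio = lambdaMinRatio
  )
  cf <- as.numeric(coef(cv, s = "lambda.min"))
  coefs <- setNames(cf[-1L], colnames(X))
  structure(
    list(
      alpha = alpha, lambda = cv$lambda.min, intercept = cf[1L],
      coefficients = coefs, selected = names(coefs)[coefs != 0],
      cvCurve = data.frame(lambda = cv$lambda, deviance = cv$cvm)
    ),
    class = "stabsig_enet_fit"
  )
}

#' Bootstrap selection frequencies at a fixed (alpha, lambda)
#'
#' Each iteration resamples the training samples with replacement to the
#' original size (redrawn, up to 50 attempts, if the resample collapses to
#' one class), standardizes the resampled features, fits the elastic net at
#' the fixed `(alpha, lambda)`, and counts every gene with a non-zero
#' coefficient as selected, recording the coefficient value.
#'
#' @param X samples x genes training matrix.
#' @param y response labels (`"R"`/`"NR"`).
#' @param alpha,lambda the fixed penalty (lambda > 0).
#' @param nBootstrap number of bootstrap iterations.
#' @param seed RNG seed.
#' @return list with `counts` (named integer, selections out of
#'   `nBootstrap`) and `coefValues` (named list of the non-zero coefficient
#'   values observed per gene).
#' @export
bootstrapSelect <- function(X, y, alpha, lambda, nBootstrap = 100L,
                            seed = 1L) {
  stopifnot(is.matrix(X), nrow(X) == length(y), lambda > 0)
  y01 <- as.integer(asResponseVector(y) == "R")
  genes <- colnames(X)
  cnt <- setNames(integer(length(genes)), genes)
  vals <- setNames(vector("list", length(genes)), genes)
  if (nBootstrap <= 0L) {
    return(list(counts = cnt, coefValues = vals))
  }
  set.seed(seed)
  path <- lambda * c(16, 8, 4, 2, 1)
  n <- nrow(X)
  for (b in seq_len(nBootstrap)) {
    for (attempt in seq_len(50L)) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y01[idx])) == 2L) break
      if (attempt == 50L) stop("bootstrap resample kept collapsing to one class")
    }
    Xb <- standardizeColumns(X[idx, , drop = FALSE])
    fit <- glmnet::glmnet(Xb, y01[idx],
      family = "binomial", alpha = alpha,
      lambda = path, standardize = FALSE
    )
    cf <- as.numeric(coef(fit, s = lambda))[-1L]
    nz <- which(cf != 0)
    if (length(nz)) {
      cnt[nz] <- cnt[nz] + 1L
      for (g in nz) {
        vals[[g]] <- c(vals[[g]], cf[g])
      }
    }
  }
  list(counts = cnt, coefValues = vals)
}

#' Top-k most frequently selected genes
#'
#' @param counts named selection counts (out of the bootstrap budget).
#' @param k stable-set size.
#' @param meanAbsCoef optional named mean |coefficient| per gene used to
#'   break count ties at the boundary (then lexicographic gene id).
#' @return character vector of up to `k` genes; genes never selected are
#'   not eligible, and fewer than `k` are returned with a warning.
#' @export
topFrequencyFeatures <- function(counts, k, meanAbsCoef = NULL) {
  stopifnot(k >= 1)
  counts <- counts[counts > 0]
  if (!length(counts)) {
    warning("no gene was ever selected")
    return(character())
  }
  if (is.null(meanAbsCoef)) {
    meanAbsCoef <- setNames(numeric(length(counts)), names(counts))
  }
  mac <- meanAbsCoef[names(counts)]
  mac[is.na(mac)] <- 0
  ord <- order(-counts, -mac, names(counts))
  out <- names(counts)[ord]
  if (length(out) < k) {
    warning("only ", length(out), " genes were ever selected (k = ", k, ")")
  }
  head(out, k)
}

#' Cross-scenario overlap of stable feature sets
#'
#' @param stableSets list over partitions, each a named list over alpha of
#'   character gene vectors (the per-scenario top-k stable sets).
#' @param mode `"strict"`: genes in the stable set of every (partition,
#'   alpha) scenario; `"fraction"`: genes in the stable set for every alpha
#'   in at least `q` of the partitions.
#' @param q partition fraction for `"fraction"` mode (default 0.5).
#' @return character vector of overlap genes (sorted).
#' @export
overlapFeatures <- function(stableSets, mode = c("strict", "fraction"),
                            q = 0.5) {
  mode <- match.arg(mode)
  if (!length(stableSets) || !length(stableSets[[1L]])) {
    stop("empty stable-set input")
  }
  if (mode == "strict") {
    return(sort(Reduce(intersect, unlist(stableSets, recursive = FALSE))))
  }
  alphas <- names(stableSets[[1L]])
  nPart <- length(stableSets)
  universe <- unique(unlist(stableSets))
  keep <- vapply(universe, function(g) {
    all(vapply(alphas, function(a) {
      mean(vapply(
        stableSets, function(pp) g %in% pp[[a]],
        logical(1L)
      )) >= q
    }, logical(1L)))
  }, logical(1L))
  sort(universe[keep])
}

#' Median coefficients of the overlap genes
#'
#' For each overlap gene, the median of all non-zero coefficient values
#' pooled across bootstrap iterations, alpha values and training partitions
#' (even counts: mean of the central pair).
#'
#' @param coefValues named list of pooled non-zero coefficient values.
#' @param overlap character vector of overlap genes.
#' @param provenance optional provenance list stored on the signature.
#' @return a [PredictiveSignature-class].
#' @export
medianCoefficients <- function(coefValues, overlap, provenance = list()) {
  if (!length(overlap)) {
    stop("overlap set is empty; no predictive signature")
  }
  med <- vapply(overlap, function(g) {
    v <- coefValues[[g]]
    if (is.null(v) || !length(v)) {
      stop("overlap gene '", g, "' has no recorded non-zero coefficient")
    }
    median(v)
  }, numeric(1L))
  PredictiveSignature(overlap, med, provenance = provenance)
}

#' Run the full stability-selection pipeline
#'
#' Composes partitioning, cross-validated elastic-net fits over the alpha
#' grid, bootstrap selection frequencies, per-scenario top-k stable sets,
#' the cross-alpha overlap (alpha = 0 is fitted for diagnostics but excluded
#' from the overlap), and median coefficients.  Fully reproducible from
#' `cfg$masterSeed`.
#'
#' @param X samples x genes preprocessed expression matrix (e.g.
#'   standardized `log2(normalized + 1)` of the integrated cohort).
#' @param y response labels (`"R"`/`"NR"`), named by sample.
#' @param cfg a [stabilityConfig()].
#' @return list with:
#'   \describe{
#'     \item{signature}{the [PredictiveSignature-class] (or `NULL` with a
#'       warning when the overlap is empty).}
#'     \item{overlap}{the overlap gene set.}
#'     \item{freqTable}{data.frame `partition`, `alpha`, `gene_id`, `count`
#'       of per-scenario bootstrap selection counts (selected genes only).}
#'     \item{stableSets}{per-(partition, alpha) top-k sets.}
#'     \item{cvSummary}{per-(partition, alpha) `lambda_min` and minimum mean
#'       CV deviance.}
#'     \item{cvCurves}{full deviance-vs-lambda curves per alpha for the
#'       first partition (regularization-path diagnostics).}
#'     \item{partitions}{the train/test splits.}
#'   }
#' @export
runStabilityPipeline <- function(X, y, cfg = stabilityConfig()) {
  stopifnot(is.matrix(X))
  if (is.null(names(y))) {
    names(y) <- rownames(X)
  }
  stopifnot(!is.null(rownames(X)), all(names(y) %in% rownames(X)))
  y <- y[rownames(X)]
  parts <- makePartitions(y, cfg)
  alphaNames <- sprintf("%.1f", cfg$alphaGrid)
  stableSets <- vector("list", cfg$nPartitions)
  freqRows <- list()
  cvRows <- list()
  cvCurves <- list()
  coefValues <- list()

  for (i in seq_len(cfg$nPartitions)) {
    train <- parts[[i]]$train
    Xtr <- X[train, , drop = FALSE]
    ytr <- y[train]
    partSets <- list()
    for (ai in seq_along(cfg$alphaGrid)) {
      a <- cfg$alphaGrid[ai]
      scen <- (i - 1L) * length(cfg$alphaGrid) + ai
      fit <- fitEnetCV(Xtr, ytr, a,
        nFolds = cfg$nFolds,
        seed = deriveSeed(cfg$masterSeed, "cv", scen),
        nLambda = cfg$nLambda, lambdaMinRatio = cfg$lambdaMinRatio
      )
      cvRows[[length(cvRows) + 1L]] <- data.frame(
        partition = i, alpha = a, lambda_min = fit$lambda,
        cv_deviance = min(fit$cvCurve$deviance)
      )
      if (i == 1L) {
        cvCurves[[alphaNames[ai]]] <- fit$cvCurve
      }
      bs <- bootstrapSelect(Xtr, ytr, a, fit$lambda,
        nBootstrap = cfg$nBootstrap,
        seed = deriveSeed(cfg$masterSeed, "bootstrap", scen)
      )
      sel <- bs$counts[bs$counts > 0]
      if (length(sel)) {
        freqRows[[length(freqRows) + 1L]] <- data.frame(
          partition = i, alpha = a, gene_id = names(sel),
          count = as.integer(sel), stringsAsFactors = FALSE
        )
      }
      if (a %in% cfg$alphasForOverlap) {
        mac <- vapply(names(sel), function(g) {
          mean(abs(bs$coefValues[[g]]))
        }, numeric(1L))
        partSets[[alphaNames[ai]]] <- suppressWarnings(
          topFrequencyFeatures(bs$counts, cfg$topK, meanAbsCoef = mac)
        )
        for (g in names(sel)) {
          coefValues[[g]] <- c(coefValues[[g]], bs$coefValues[[g]])
        }
      }
    }
    stableSets[[i]] <- partSets
  }

  overlap <- overlapFeatures(stableSets,
    mode = cfg$overlapMode,
    q = cfg$overlapQ
  )
  signature <- NULL
  if (length(overlap)) {
    signature <- medianCoefficients(coefValues, overlap,
      provenance = list(
        config = unclass(cfg),
        n_scenarios = cfg$nPartitions * length(cfg$alphasForOverlap)
      )
    )
  } else {
    warning("cross-alpha overlap set is empty; no predictive signature")
  }
  list(
    signature = signature,
    overlap = overlap,
    freqTable = if (length(freqRows)) {
      do.call(rbind, freqRows)
    } else {
      data.frame(
        partition = integer(), alpha = numeric(),
        gene_id = character(), count = integer()
      )
    },
    stableSets = stableSets,
    coefValues = coefValues,
    cvSummary = do.call(rbind, cvRows),
    cvCurves = cvCurves,
    partitions = parts
  )
}
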