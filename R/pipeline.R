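#' @include AllClasses.R
NULL

#' End-to-end pipeline configuration
#'
#' The pipeline runs either on files (`countsPath` + `metadataPath`) or on a
#' simulated cohort (`sim`), then: batch adjustment on raw counts,
#' median-of-ratios normalization, expression filtering, optional
#' correlation-signature derivation, stability selection on the treated
#' R/NR samples, response scoring, subsampled ROC validation, and
#' fixed-threshold classification.  Every random stage derives its seed
#' deterministically from `masterSeed`.
#'
#' @param countsPath,metadataPath input files (TSV; see
#'   [readCountMatrix()] / [readSampleMetadata()]), or `NULL` when `sim` is
#'   given.
#' @param sim a [simConfig()] to simulate the input cohort instead.
#' @param minCount,minSampleFrac gene-filter thresholds (defaults 10 /
#'   0.40).
#' @param batchMethod [batchAdjust()] method (default `"none"`).
#' @param deriveSignatures also derive per-outcome correlation signatures
#'   (default `TRUE`).
#' @param signaturePThreshold raw p threshold for correlation signatures.
#' @param stability a [stabilityConfig()].
#' @param nIterations,subsetSize ROC validation budget (defaults 1000 / 20).
#' @param fixedThreshold fixed classification threshold (default -0.01).
#' @param masterSeed master seed for all stages.
#' @param outDir output directory for artifacts and the run manifest.
#' @return a `stabsig_pipeline_config` list.
#' @export
pipelineConfig <- function(countsPath = NULL, metadataPath = NULL, sim = NULL,
                           minCount = 10, minSampleFrac = 0.40,
                           batchMethod = "none", deriveSignatures = TRUE,
                           signaturePThreshold = 0.05,
                           stability = stabilityConfig(),
                           nIterations = 1000L, subsetSize = 20L,
                           fixedThreshold = -0.01, masterSeed = 1L,
                           outDir = tempfile("stabsig_run_")) {
  if (is.null(sim) && (is.null(countsPath) || is.null(metadataPath))) {
    stop("provide countsPath + metadataPath, or a simulation config")
  }
  cfg <- list(
    countsPath = countsPath, metadataPath = metadataPath, sim = sim,
    minCount = minCount, minSampleFrac = minSampleFrac,
    batchMethod = batchMethod, deriveSignatures = deriveSignatures,
    signaturePThreshold = signaturePThreshold, stability = stability,
    nIterations = as.integer(nIterations), subsetSize = as.integer(subsetSize),
    fixedThreshold = fixedThreshold, masterSeed = as.integer(masterSeed),
    outDir = outDir
  )
  class(cfg) <- "stabsig_pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes the staged workflow described in [pipelineConfig()], writing
#' every artifact as TSV with an md5 digest, and returns a run manifest.
#' Re-running with an identical configuration (including `masterSeed`)
#' reproduces identical digests.
#'
#' @param cfg a [pipelineConfig()].
#' @return invisibly, a list with `manifest` (stages, artifact digests,
#'   wall times, warnings) and `results` (the in-memory stage outputs:
#'   `cohort`, `signature`, `scores`, `validation`, `classification`,
#'   `signatures` when derived).
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "stabsig_pipeline_config"))
  # launch-time validation: fail before creating any output
  if (is.null(cfg$sim)) {
    for (p in c(cfg$countsPath, cfg$metadataPath)) {
      if (!file.exists(p)) {
        stop("input file not found: ", p)
      }
    }
  }
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  results <- list()
  warningsSeen <- character()
  artifact <- function(name, writer) {
    path <- file.path(cfg$outDir, name)
    writer(path)
    path
  }
  runStage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    out <- withCallingHandlers(
      tryCatch(fun(), error = function(e) {
        stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
      }),
      warning = function(w) {
        warningsSeen <<- c(
          warningsSeen,
          paste0(name, ": ", conditionMessage(w))
        )
        invokeRestart("muffleWarning")
      }
    )
    stages[[name]] <<- list(
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 3)
    )
    out
  }

  # -- load / simulate -------------------------------------------------------
  cohort <- runStage("load", function() {
    if (!is.null(cfg$sim)) {
      sim <- simulateCohort(cfg$sim)
      results$truth <<- sim$truth
      sim$cohort
    } else {
      cm <- readCountMatrix(cfg$countsPath)
      md <- readSampleMetadata(cfg$metadataPath)
      ResponseCohort(cm, md)
    }
  })

  # -- batch adjust on raw counts, then normalize, then filter ---------------
  cohort <- runStage("preprocess", function() {
    cm <- counts(cohort)
    batch <- as.character(colData(cohort)$batch)
    if (cfg$batchMethod != "none" && !all(is.na(batch))) {
      cm <- batchAdjust(cm, batch, method = cfg$batchMethod)
      cohortNew <- ResponseCohort(cm, as.data.frame(colData(cohort)))
    } else {
      cohortNew <- cohort
    }
    cohortNew <- normalizeCohort(cohortNew)
    flt <- filterGenes(cohortNew,
      minCount = cfg$minCount,
      minSampleFrac = cfg$minSampleFrac
    )
    results$preprocessReport <<- flt$report
    flt$x
  })
  results$cohort <- cohort

  logExpr <- normalizedValues(cohort, log2 = TRUE)
  cd <- as.data.frame(colData(cohort))
  treated <- cd$arm == "treated" & cd$response %in% c("R", "NR")

  # -- optional correlation signatures ---------------------------------------
  if (isTRUE(cfg$deriveSignatures)) {
    results$signatures <- runStage("signatures", function() {
      out <- list()
      ttd <- cd$time_to_diagnosis
      if (!is.null(ttd) && sum(is.finite(ttd[treated])) >= 3L) {
        sigs <- pearsonSignature(
          logExpr[, treated, drop = FALSE],
          setNames(ttd[treated], cd$sample_id[treated]),
          pThreshold = cfg$signaturePThreshold, name = "time_to_dx"
        )
        placebo <- cd$arm == "placebo" & is.finite(ttd)
        if (sum(placebo) >= 3L) {
          sigs$positive <- excludePlaceboCorrelated(
            sigs$positive, logExpr[, placebo, drop = FALSE],
            setNames(ttd[placebo], cd$sample_id[placebo])
          )
          sigs$negative <- excludePlaceboCorrelated(
            sigs$negative, logExpr[, placebo, drop = FALSE],
            setNames(ttd[placebo], cd$sample_id[placebo])
          )
        }
        artifact("signature_positive.tsv", function(p) {
          writeGeneSignature(sigs$positive, p)
        })
        artifact("signature_negative.tsv", function(p) {
          writeGeneSignature(sigs$negative, p)
        })
        out <- sigs
      }
      out
    })
  }

  # -- stability selection ---------------------------------------------------
  stab <- runStage("stability_selection", function() {
    if (sum(treated) < 4L) {
      stop("too few labeled treated samples")
    }
    X <- t(logExpr[, treated, drop = FALSE])
    yy <- setNames(cd$response[treated], cd$sample_id[treated])
    scfg <- cfg$stability
    scfg$masterSeed <- deriveSeed(cfg$masterSeed, "partition")
    runStabilityPipeline(X, yy, scfg)
  })
  results$stability <- stab
  if (is.null(stab$signature)) {
    stop("stage 'stability_selection' produced an empty overlap set")
  }
  artifact("predictive_signature.tsv", function(p) {
    writePredictiveSignature(stab$signature, p)
  })
  artifact("selection_frequencies.tsv", function(p) {
    write.table(stab$freqTable, p, sep = "\t", quote = FALSE, row.names = FALSE)
  })

  # -- scoring and validation ------------------------------------------------
  scores <- runStage("scoring", function() {
    std <- standardizeExpression(logExpr[, treated, drop = FALSE])
    responseScore(std, stab$signature, metadata = cd[treated, , drop = FALSE])
  })
  results$scores <- scores
  artifact("response_scores.tsv", function(p) {
    write.table(scores, p, sep = "\t", quote = FALSE, row.names = FALSE)
  })

  results$validation <- runStage("validation", function() {
    resampledValidation(scores,
      nIterations = cfg$nIterations,
      subsetSize = min(cfg$subsetSize, nrow(scores)),
      seed = deriveSeed(cfg$masterSeed, "validate")
    )
  })
  results$classification <- runStage("classification", function() {
    classifyFixedThreshold(scores, threshold = cfg$fixedThreshold)
  })
  artifact("classification.tsv", function(p) {
    write.table(results$classification, p,
      sep = "\t", quote = FALSE,
      row.names = FALSE
    )
  })

  # -- manifest --------------------------------------------------------------
  files <- sort(list.files(cfg$outDir, pattern = "\\.tsv$", full.names = TRUE))
  digests <- tools::md5sum(files)
  names(digests) <- basename(names(digests))
  manifest <- list(
    package_version = as.character(packageVersion("stabsig")),
    master_seed = cfg$masterSeed,
    stages = stages,
    artifacts = as.list(digests),
    warnings = warningsSeen
  )
  manifestPath <- file.path(cfg$outDir, "manifest.txt")
  writeLines(c(
    paste0("package_version: ", manifest$package_version),
    paste0("master_seed: ", manifest$master_seed),
    paste0("stage: ", names(stages), " (", vapply(
      stages, function(s) s$elapsed_s,
      numeric(1L)
    ), " s)"),
    paste0("artifact: ", names(digests), " md5=", unname(digests)),
    if (length(warningsSeen)) paste0("warning: ", warningsSeen) else character()
  ), manifestPath)
  invisible(list(manifest = manifest, results = results))
}
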