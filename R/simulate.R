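#' @include AllClasses.R
NULL

# Outcome model constants: C-peptide AUC as % of baseline sits near 100 for
# responders-to-be and declines with progression; time to diagnosis is in
# months.  Slopes couple both outcomes to the same latent response score.
CPEP_INTERCEPT <- 100
CPEP_SLOPE <- 60
TTD_INTERCEPT <- 18
TTD_SLOPE <- 12

#' Simulation configuration for a two-study response cohort
#'
#' Defines the statistical structure the downstream analysis assumes: two
#' bulk RNA-seq studies with negative-binomial counts, log-normal library
#' sizes, per-(gene, batch) multiplicative batch effects, treated and
#' placebo/control arms, binary responder status, and continuous clinical
#' outcomes coupled to a set of planted signature genes.
#'
#' @param nGenes total number of genes.
#' @param nSignalPos,nSignalNeg numbers of planted genes up- resp.
#'   down-regulated in responders.
#' @param studies named list; each study is a list with elements
#'   `treated = c(R = , NR = )`, optionally `placebo` and/or `control`
#'   (sample counts), and `nBatches` (default 1).
#' @param baselineLogMean `c(mean =, sd =)` of the natural-log baseline mean
#'   expression across genes.
#' @param dispersion negative-binomial dispersion phi (> 0) in the
#'   `variance = mu + phi * mu^2` parameterization.
#' @param librarySizeLogSd sd of log library-size factors (>= 0).
#' @param batchLogFcSd sd of per-(gene, batch) log2 fold shifts (>= 0).
#' @param effectLog2fc planted absolute log2 fold change between responders
#'   and nonresponders.
#' @param outcomeNoiseSd sd of the C-peptide outcome noise, in percent of
#'   baseline; the time-to-diagnosis noise is scaled by the slope ratio so
#'   both outcomes share the same signal-to-noise.
#' @param placeboProgressionGenes number of genes whose expression tracks
#'   disease progression in the placebo arm only.
#' @param overlapFraction fraction of the placebo-progression genes drawn
#'   from the planted set (so the placebo-exclusion filter has work to do).
#' @param seed integer seed; the whole cohort is a pure function of the
#'   configuration including this seed.
#' @return a `stabsig_sim_config` list.
#' @export
simConfig <- function(nGenes = 2000L,
                      nSignalPos = 25L,
                      nSignalNeg = 25L,
                      studies = list(
                        AbATE = list(
                          treated = c(R = 14L, NR = 16L),
                          control = 15L, nBatches = 2L
                        ),
                        TN10 = list(
                          treated = c(R = 22L, NR = 20L),
                          placebo = 31L, nBatches = 1L
                        )
                      ),
                      baselineLogMean = c(mean = 3, sd = 1.5),
                      dispersion = 0.1,
                      librarySizeLogSd = 0.3,
                      batchLogFcSd = 0.2,
                      effectLog2fc = 1,
                      outcomeNoiseSd = 20,
                      placeboProgressionGenes = 20L,
                      overlapFraction = 0.5,
                      seed = 1L) {
  cfg <- list(
    nGenes = as.integer(nGenes),
    nSignalPos = as.integer(nSignalPos),
    nSignalNeg = as.integer(nSignalNeg),
    studies = studies,
    baselineLogMean = baselineLogMean,
    dispersion = dispersion,
    librarySizeLogSd = librarySizeLogSd,
    batchLogFcSd = batchLogFcSd,
    effectLog2fc = effectLog2fc,
    outcomeNoiseSd = outcomeNoiseSd,
    placeboProgressionGenes = as.integer(placeboProgressionGenes),
    overlapFraction = overlapFraction,
    seed = as.integer(seed)
  )
  class(cfg) <- "stabsig_sim_config"
  validateSimConfig(cfg)
  cfg
}

validateSimConfig <- function(cfg) {
  stopifnot(
    cfg$nGenes >= 1L,
    cfg$nSignalPos >= 0L, cfg$nSignalNeg >= 0L,
    cfg$nSignalPos + cfg$nSignalNeg <= cfg$nGenes,
    cfg$dispersion > 0,
    cfg$librarySizeLogSd >= 0, cfg$batchLogFcSd >= 0,
    cfg$effectLog2fc >= 0, cfg$outcomeNoiseSd >= 0,
    cfg$overlapFraction >= 0, cfg$overlapFraction <= 1,
    length(cfg$studies) >= 1L
  )
  for (nm in names(cfg$studies)) {
    st <- cfg$studies[[nm]]
    tr <- st$treated
    if (is.null(tr) || !all(c("R", "NR") %in% names(tr))) {
      stop("study '", nm, "' must define treated = c(R =, NR =)")
    }
    if (any(tr[c("R", "NR")] < 1L)) {
      stop("study '", nm, "' has an empty treated response stratum")
    }
  }
  invisible(cfg)
}

#' Simulate a two-study response cohort with planted signal genes
#'
#' Counts are drawn as `NB(mean = s_j * b_[batch(j),g] * mu_g *
#' 2^(delta_g * z_j), variance = mu + phi mu^2)` with log-normal library
#' sizes `s_j`, per-(gene, batch) log-normal shifts `b`, `z_j = +1/2` for
#' responders and `-1/2` for nonresponders (0 for placebo/control), and
#' `delta_g = +/- effectLog2fc` on the planted genes, 0 elsewhere.  Clinical
#' outcomes are linear in the per-sample latent response score plus Gaussian
#' noise, truncated at zero.  Placebo samples carry progression-linked shifts
#' (`2^(effectLog2fc * w_j)` with latent progression `w_j ~ N(0, 0.5^2)`) on
#' the placebo-progression genes only.
#'
#' @param config a [simConfig()] object.
#' @return list with elements `cohort` (a [ResponseCohort-class]) and
#'   `truth` (a `stabsig_ground_truth` list: `planted_pos`, `planted_neg`,
#'   `placebo_progression_genes`, per-sample `latent_score`).
#' @examples
#' sim <- simulateCohort(simConfig(nGenes = 50, seed = 7))
#' sim$cohort
#' @export
simulateCohort <- function(config) {
  validateSimConfig(config)
  set.seed(config$seed)
  p <- config$nGenes
  genes <- sprintf("gene_%05d", seq_len(p))

  # planted and placebo-progression gene sets are deterministic in the
  # configuration so cohorts simulated under different seeds share them
  plantedPos <- genes[seq_len(config$nSignalPos)]
  plantedNeg <- genes[config$nSignalPos + seq_len(config$nSignalNeg)]
  planted <- c(plantedPos, plantedNeg)
  nOverlap <- min(round(config$overlapFraction * config$placeboProgressionGenes),
    length(planted))
  nFresh <- config$placeboProgressionGenes - nOverlap
  freeStart <- config$nSignalPos + config$nSignalNeg
  if (freeStart + nFresh > p) {
    stop("not enough genes for the placebo-progression set")
  }
  placeboGenes <- c(
    head(planted, nOverlap),
    genes[freeStart + seq_len(nFresh)]
  )

  delta <- setNames(numeric(p), genes)
  delta[plantedPos] <- config$effectLog2fc
  delta[plantedNeg] <- -config$effectLog2fc

  muG <- exp(rnorm(p,
    mean = config$baselineLogMean[["mean"]],
    sd = config$baselineLogMean[["sd"]]
  ))

  # assemble the sample sheet
  rows <- list()
  for (studyName in names(config$studies)) {
    st <- config$studies[[studyName]]
    addRows <- function(arm, response, n) {
      if (is.null(n) || n == 0L) {
        return(NULL)
      }
      data.frame(
        study = studyName, arm = arm, response = response,
        n = seq_len(n), stringsAsFactors = FALSE
      )
    }
    rows[[length(rows) + 1L]] <- addRows("treated", "R", st$treated[["R"]])
    rows[[length(rows) + 1L]] <- addRows("treated", "NR", st$treated[["NR"]])
    rows[[length(rows) + 1L]] <- addRows("placebo", "unknown", st$placebo)
    rows[[length(rows) + 1L]] <- addRows("control", "unknown", st$control)
  }
  meta <- do.call(rbind, rows)
  n <- nrow(meta)
  meta$sample_id <- sprintf(
    "%s_%s_%s_%02d", meta$study, meta$arm, meta$response, meta$n
  )
  meta$n <- NULL

  # batches: samples of a study spread cyclically over its batches
  meta$batch <- NA_character_
  for (studyName in names(config$studies)) {
    nb <- config$studies[[studyName]]$nBatches
    if (is.null(nb)) nb <- 1L
    idx <- which(meta$study == studyName)
    meta$batch[idx] <- sprintf(
      "%s_b%d", studyName, rep_len(seq_len(nb), length(idx))
    )
  }

  # latent response score: +/- 1/2 for treated R/NR, -1/2 for untreated
  # controls (who progress), N(0, 0.5^2) progression score for placebo
  z <- ifelse(meta$arm == "treated" & meta$response == "R", 0.5,
    ifelse(meta$arm == "treated" & meta$response == "NR", -0.5, 0)
  )
  latent <- z
  latent[meta$arm == "control"] <- -0.5
  iPlacebo <- which(meta$arm == "placebo")
  w <- rnorm(length(iPlacebo), 0, 0.5)
  latent[iPlacebo] <- w

  # clinical outcomes, truncated at zero
  noise <- function(sdv) rnorm(n, 0, sdv)
  ttdNoiseSd <- config$outcomeNoiseSd * TTD_SLOPE / CPEP_SLOPE
  cpep6 <- pmax(0, CPEP_INTERCEPT + CPEP_SLOPE * latent +
    noise(config$outcomeNoiseSd))
  cpep12 <- pmax(0, CPEP_INTERCEPT + CPEP_SLOPE * latent +
    noise(config$outcomeNoiseSd))
  ttd <- pmax(0, TTD_INTERCEPT + TTD_SLOPE * latent + noise(ttdNoiseSd))
  meta$cpep_auc_pct_baseline_m6 <- ifelse(meta$arm == "placebo", NA, cpep6)
  meta$cpep_auc_pct_baseline_m12 <- ifelse(meta$arm == "placebo", NA, cpep12)
  meta$time_to_diagnosis <- ifelse(meta$arm == "control", NA, ttd)
  meta$age <- sample(8:45, n, replace = TRUE)
  meta$sex <- sample(c("F", "M"), n, replace = TRUE)

  # expression means
  s <- exp(rnorm(n, 0, config$librarySizeLogSd))
  batches <- unique(meta$batch)
  batchFac <- matrix(1, p, length(batches), dimnames = list(genes, batches))
  if (config$batchLogFcSd > 0) {
    for (b in batches) {
      batchFac[, b] <- 2^rnorm(p, 0, config$batchLogFcSd)
    }
  }
  mu <- outer(muG, s) * batchFac[, meta$batch, drop = FALSE] *
    2^(delta %o% z)
  if (length(iPlacebo) && length(placeboGenes)) {
    mu[placeboGenes, iPlacebo] <- mu[placeboGenes, iPlacebo, drop = FALSE] *
      rep(2^(config$effectLog2fc * w), each = length(placeboGenes))
  }

  countsVec <- rnbinom(p * n, mu = as.numeric(mu), size = 1 / config$dispersion)
  countsMat <- matrix(countsVec, p, n, dimnames = list(genes, meta$sample_id))

  truth <- list(
    planted_pos = plantedPos,
    planted_neg = plantedNeg,
    placebo_progression_genes = placeboGenes,
    latent_score = setNames(latent, meta$sample_id)
  )
  class(truth) <- "stabsig_ground_truth"

  list(cohort = ResponseCohort(countsMat, meta), truth = truth)
}

#' Recall and precision of a selected gene set against the planted truth
#'
#' @param selected character vector of selected gene identifiers.
#' @param truth ground truth as returned by [simulateCohort()].
#' @return named numeric `c(recall =, precision =)`.  Recall is
#'   `|selected & planted| / |planted|`, precision
#'   `|selected & planted| / |selected|`; an empty selection has precision 1
#'   by convention, flagged via attribute `"empty_selection"`.
#' @export
truthOverlap <- function(selected, truth) {
  stopifnot(inherits(truth, "stabsig_ground_truth"))
  planted <- c(truth$planted_pos, truth$planted_neg)
  hit <- length(intersect(selected, planted))
  recall <- if (length(planted)) hit / length(planted) else 0
  if (length(selected) == 0L) {
    out <- c(recall = recall, precision = 1)
    attr(out, "empty_selection") <- TRUE
    return(out)
  }
  c(recall = recall, precision = hit / length(selected))
}
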