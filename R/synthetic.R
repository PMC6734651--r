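## Seeded synthetic studies with the statistical structure the analysis
## assumes: bimodal marker genes, a planted sparse low-low quadrant between
## a marker gene and a VIM-like target, tissue-class structure (CRC, polyp,
## IBD, normal mucosa), molecular-label enrichment in the marker-low
## subgroup, and proportional-hazards survival with group-dependent hazard
## and independent uniform censoring. Every draw is a pure function of
## (config, seed); each gene and cohort gets a sub-seed derived from the
## master seed and its index so adding genes never perturbs existing ones.

#' Synthetic study configuration
#'
#' Defaults emulate the study conditions of the analysis at desk scale:
#' a reduced-scale array population (500 CRC, 20 polyp, 90 IBD, 80 normal),
#' bimodal genes with modes at 5 and 9 log2 units and sigma = 0.5 (4-sigma
#' separation), a marker-low fraction of 0.226 with sparse-quadrant leak
#' eps = 0.02 into marker-low/target-low, and two survival cohorts of
#' n = 889 and n = 691 with planted marker log-hazard-ratios ln(1.37) and
#' ln(4.05) and ~70 percent censoring.
#'
#' @param nCRC,nPolyp,nIBD,nNormal samples per tissue class.
#' @param nGenes total genes; \code{nBimodal} of them bimodal background
#'   genes, \code{nDE} differentially expressed in CRC by \code{deShift}
#'   log2 units, the rest unimodal background.
#' @param nBimodal number of generic bimodal genes.
#' @param modeLow,modeHigh,sigma mixture modes and common SD (log2 units).
#' @param markerGene,targetGene ids of the planted marker and its
#'   implication target (the VIM-like gene).
#' @param piLow marker-low fraction among CRC samples.
#' @param eps sparse-quadrant leak: P(target LOW | marker LOW).
#' @param targetLowGivenMarkerHigh P(target LOW | marker HIGH).
#' @param bimodalLowFraction low-mode fraction of generic bimodal genes.
#' @param nDE,deShift differential-expression spec (CRC vs. normal/IBD).
#' @param backgroundMean,backgroundSd unimodal background distribution.
#' @param msiBase,brafBase marginal MSI / BRAF-mutant rates in marker-high
#'   CRC; \code{enrichmentOR} is the odds ratio in the marker-low group.
#' @param plantImplication plant the marker/target implication (FALSE gives
#'   a zero-structure null study: every gene unimodal, no planted pair).
#' @param nDiscovery,nValidation survival cohort sizes.
#' @param betaDiscovery,betaValidation planted marker log hazard ratios.
#' @param piLowDiscovery,piLowValidation marker-low fractions of the
#'   survival cohorts.
#' @param baselineHazard events per month in the reference group.
#' @param betaStage,betaAge60 nuisance log HRs (per stage increase; age
#'   >= 60).
#' @param censoringRate target fraction censored (uniform censoring).
#' @param horizonMonths accrual horizon bounding the censoring window.
#' @param stageProbs,chemoProbs categorical margins for stage and chemo.
#' @return a validated config list of class \code{StudyConfig}.
#' @export
studyConfig <- function(nCRC = 500L, nPolyp = 20L, nIBD = 90L, nNormal = 80L,
                        nGenes = 500L, nBimodal = 50L,
                        modeLow = 5, modeHigh = 9, sigma = 0.5,
                        markerGene = "MARKER1", targetGene = "VIMLIKE",
                        piLow = 0.226, eps = 0.02,
                        targetLowGivenMarkerHigh = 0.5,
                        bimodalLowFraction = 0.3,
                        nDE = 3L, deShift = 1.5,
                        backgroundMean = 7, backgroundSd = 1,
                        msiBase = 0.15, brafBase = 0.10, enrichmentOR = 4,
                        plantImplication = TRUE,
                        nDiscovery = 889L, nValidation = 691L,
                        betaDiscovery = log(1.37),
                        betaValidation = log(4.05),
                        piLowDiscovery = 205 / 889,
                        piLowValidation = 229 / 691,
                        baselineHazard = 0.01,
                        betaStage = log(1.8), betaAge60 = log(1.1),
                        censoringRate = 0.7, horizonMonths = 120,
                        stageProbs = c(I = 0.10, II = 0.52, III = 0.38),
                        chemoProbs = c(yes = 0.45, no = 0.40,
                                       missing = 0.15)) {
  cfg <- as.list(environment())
  stopIfNot(cfg$piLow > 0 && cfg$piLow < 1, "piLow must be in (0, 1)")
  stopIfNot(cfg$eps >= 0 && cfg$eps < 1, "eps must be in [0, 1)")
  stopIfNot(cfg$sigma > 0, "sigma must be positive")
  stopIfNot(cfg$censoringRate >= 0 && cfg$censoringRate < 1,
            "censoringRate must be in [0, 1)")
  nPlanted <- cfg$nBimodal + cfg$nDE + 2L
  stopIfNot(nPlanted <= cfg$nGenes,
            "more planted genes (%d) than nGenes (%d)", nPlanted, cfg$nGenes)
  stopIfNot(abs(sum(cfg$stageProbs) - 1) < 1e-8 &&
              abs(sum(cfg$chemoProbs) - 1) < 1e-8,
            "stageProbs and chemoProbs must each sum to 1")
  class(cfg) <- "StudyConfig"
  cfg
}

drawEnriched <- function(base, or, enriched) {
  odds <- base / (1 - base) * ifelse(enriched, or, 1)
  p <- odds / (1 + odds)
  stats::rbinom(length(p), 1L, p) == 1L
}

#' Generate a synthetic expression matrix with planted truth
#'
#' Background genes are unimodal Gaussian; bimodal genes are two-Gaussian
#' mixtures. The planted pair is generated by conditional sampling of the
#' target's mode given the marker's mode (leak \code{eps}), never by
#' post-hoc editing, so both marginals stay bimodal. DE genes are shifted
#' in CRC relative to normal and IBD tissue. MSI and BRAF labels are drawn
#' with the configured enrichment odds in the marker-low group.
#'
#' @param config a \code{\link{studyConfig}}.
#' @param seed integer master seed.
#' @return list with \code{se} (SummarizedExperiment, annotations in
#'   \code{colData}), \code{annotations} (data.frame) and \code{truth}
#'   (planted parameters: marker/target membership, bimodal gene ids, true
#'   threshold, DE gene ids).
#' @export
generateExpression <- function(config, seed) {
  stopIfNot(inherits(config, "StudyConfig"), "config must be a StudyConfig")
  cfg <- config
  classes <- rep(c("CRC", "polyp", "IBD", "normal"),
                 c(cfg$nCRC, cfg$nPolyp, cfg$nIBD, cfg$nNormal))
  nS <- length(classes)
  ids <- sprintf("S%04d", seq_len(nS))
  isCRC <- classes == "CRC"

  ## stream 0: memberships and molecular labels
  set.seed(subSeed(seed, 0L))
  markerLow <- rep(NA, nS)
  targetLow <- rep(NA, nS)
  markerLow[isCRC] <- stats::runif(sum(isCRC)) < cfg$piLow
  targetLow[isCRC] <- ifelse(markerLow[isCRC],
                             stats::runif(sum(isCRC)) < cfg$eps,
                             stats::runif(sum(isCRC)) <
                               cfg$targetLowGivenMarkerHigh)
  targetLow[!isCRC] <- stats::runif(sum(!isCRC)) < 0.5
  msi <- braf <- rep("unknown", nS)
  kras <- tp53 <- rep("unknown", nS)
  msi[isCRC] <- ifelse(
    drawEnriched(cfg$msiBase, cfg$enrichmentOR, markerLow[isCRC]),
    "MSI", "MSS")
  braf[isCRC] <- ifelse(
    drawEnriched(cfg$brafBase, cfg$enrichmentOR, markerLow[isCRC]),
    "mutant", "wildtype")
  kras[isCRC] <- ifelse(stats::runif(sum(isCRC)) < 0.4, "mutant", "wildtype")
  tp53[isCRC] <- ifelse(stats::runif(sum(isCRC)) < 0.5, "mutant", "wildtype")

  ## gene roster: marker, target, generic bimodal, DE, background
  nOther <- cfg$nGenes - 2L
  geneIds <- c(cfg$markerGene, cfg$targetGene,
               sprintf("g%04d", seq_len(nOther)))
  bimodalGenes <- geneIds[2L + seq_len(cfg$nBimodal)]
  deGenes <- geneIds[2L + cfg$nBimodal + seq_len(cfg$nDE)]
  m <- matrix(NA_real_, nrow = cfg$nGenes, ncol = nS,
              dimnames = list(geneIds, ids))
  mix <- function(low) ifelse(low, cfg$modeLow, cfg$modeHigh) +
    stats::rnorm(length(low), 0, cfg$sigma)
  for (k in seq_len(cfg$nGenes)) {
    set.seed(subSeed(seed, k))
    gid <- geneIds[k]
    if (cfg$plantImplication && gid == cfg$markerGene) {
      ## bimodal in CRC per membership; low mode outside CRC (drives the
      ## CRC vs normal/IBD differential expression of the marker)
      low <- ifelse(isCRC, markerLow, TRUE)
      m[k, ] <- mix(low)
    } else if (cfg$plantImplication && gid == cfg$targetGene) {
      m[k, ] <- mix(targetLow)
    } else if (gid %in% bimodalGenes) {
      m[k, ] <- mix(stats::runif(nS) < cfg$bimodalLowFraction)
    } else if (gid %in% deGenes) {
      m[k, ] <- stats::rnorm(nS, cfg$backgroundMean, cfg$backgroundSd) +
        ifelse(isCRC, cfg$deShift, 0)
    } else {
      m[k, ] <- stats::rnorm(nS, cfg$backgroundMean, cfg$backgroundSd)
    }
  }
  ann <- data.frame(sample_id = ids, tissue_class = classes, msi = msi,
                    kras = kras, braf = braf, tp53 = tp53,
                    cohort_id = "synthetic", stringsAsFactors = FALSE)
  rownames(ann) <- ids
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = m), colData = S4Vectors::DataFrame(ann))
  truth <- list(
    markerGene = cfg$markerGene, targetGene = cfg$targetGene,
    planted = cfg$plantImplication,
    markerLow = stats::setNames(markerLow, ids),
    targetLow = stats::setNames(targetLow, ids),
    piLow = cfg$piLow, eps = cfg$eps,
    bimodalGenes = bimodalGenes, deGenes = deGenes, deShift = cfg$deShift,
    trueThreshold = (cfg$modeLow + cfg$modeHigh) / 2)
  list(se = se, annotations = ann, truth = truth)
}

## Solve the uniform-censoring window width so that the expected censored
## fraction matches the target: P(C < T) = mean_i (1 - exp(-lambda_i h)) /
## (lambda_i h), decreasing in h.
censoringWindow <- function(lambda, target, horizon) {
  f <- function(h) mean((1 - exp(-lambda * h)) / (lambda * h)) - target
  if (f(horizon) > 0) {
    stop(sprintf(
      "target censoring rate %.2f unreachable within horizon %g months (minimum %.2f)",
      target, horizon, f(horizon) + target), call. = FALSE)
  }
  stats::uniroot(f, c(1e-8, horizon), tol = 1e-10)$root
}

#' Generate a synthetic clinical table under proportional hazards
#'
#' Event times are exponential with hazard
#' \eqn{h_0 \exp(\beta 1[low] + \beta_{stage}(stage-1) + \beta_{60}
#' 1[age \ge 60])}; censoring is independent Uniform(0, h) with h solved so
#' the expected censored fraction equals \code{config$censoringRate}
#' (error if unreachable within the accrual horizon). Age, sex, stage and
#' chemo are drawn from the configured margins; a disease-specific (DSS)
#' endpoint is drawn from the same linear predictor.
#'
#' @param config a \code{\link{studyConfig}}.
#' @param trueGroups factor/character of \code{"low"}/\code{"high"} per
#'   patient.
#' @param seed integer seed.
#' @param beta planted marker log hazard ratio (default
#'   \code{config$betaDiscovery}).
#' @return clinical data.frame (same columns as
#'   \code{\link{readClinicalTable}} plus \code{group}).
#' @export
generateClinical <- function(config, trueGroups, seed,
                             beta = config$betaDiscovery) {
  stopIfNot(inherits(config, "StudyConfig"), "config must be a StudyConfig")
  cfg <- config
  grp <- as.character(trueGroups)
  stopIfNot(all(grp %in% c("low", "high")),
            "trueGroups must be 'low'/'high'")
  n <- length(grp)
  set.seed(subSeed(seed, 0L))
  age <- pmin(pmax(round(stats::rnorm(n, 65, 12)), 30), 90)
  sex <- ifelse(stats::runif(n) < 0.5, "F", "M")
  stage <- sample(names(cfg$stageProbs), n, TRUE, cfg$stageProbs)
  chemo <- sample(names(cfg$chemoProbs), n, TRUE, cfg$chemoProbs)
  location <- ifelse(stats::runif(n) < 0.55, "colon", "rectum")
  grade <- sample(c("well", "moderate", "poor"), n, TRUE,
                  c(0.05, 0.65, 0.30))
  stageNum <- match(stage, c("I", "II", "III"))
  lp <- beta * (grp == "low") + cfg$betaStage * (stageNum - 1) +
    cfg$betaAge60 * (age >= 60)
  lambda <- cfg$baselineHazard * exp(lp)
  tDfs <- stats::rexp(n, lambda)
  tDss <- stats::rexp(n, lambda)
  if (cfg$censoringRate == 0) {
    cens <- rep(Inf, n)
  } else {
    h <- censoringWindow(lambda, cfg$censoringRate, cfg$horizonMonths)
    cens <- stats::runif(n, 0, h)
  }
  out <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    dfs_months = pmin(tDfs, cens),
    dfs_event = as.integer(tDfs <= cens),
    dss_months = pmin(tDss, cens),
    dss_event = as.integer(tDss <= cens),
    stage = factor(stage, levels = c("I", "II", "III"), ordered = TRUE),
    age = age, sex = sex, location = location, grade = grade,
    chemo = chemo,
    cea = round(exp(stats::rnorm(n, log(3.5) + 0.2 * (grp == "low"), 1)), 2),
    ca199 = round(exp(stats::rnorm(n, log(12) + 0.2 * (grp == "low"), 1)), 2),
    group = factor(grp, levels = c("low", "high")),
    stringsAsFactors = FALSE)
  rownames(out) <- out$patient_id
  out
}

#' Generate a full synthetic study
#'
#' Produces the array population (expression + annotations + truth) and
#' two survival cohorts (discovery and validation) sharing the planted
#' truth but with independent noise. When \code{outDir} is given, writes
#' \code{matrix.tsv}, \code{annotations.tsv},
#' \code{clinical_discovery.tsv}, \code{clinical_validation.tsv} and
#' \code{truth.json}.
#'
#' @param config a \code{\link{studyConfig}}.
#' @param seed integer master seed (all randomness derives from it).
#' @param outDir optional output directory.
#' @return list with \code{se}, \code{annotations},
#'   \code{clinicalDiscovery}, \code{clinicalValidation}, \code{truth}.
#' @export
generateStudy <- function(config, seed, outDir = NULL) {
  stopIfNot(inherits(config, "StudyConfig"), "config must be a StudyConfig")
  cfg <- config
  expr <- generateExpression(cfg, subSeed(seed, 1L))
  set.seed(subSeed(seed, 2L))
  gDisc <- ifelse(stats::runif(cfg$nDiscovery) < cfg$piLowDiscovery,
                  "low", "high")
  clinDisc <- generateClinical(cfg, gDisc, subSeed(seed, 3L),
                               beta = cfg$betaDiscovery)
  set.seed(subSeed(seed, 4L))
  gVal <- ifelse(stats::runif(cfg$nValidation) < cfg$piLowValidation,
                 "low", "high")
  clinVal <- generateClinical(cfg, gVal, subSeed(seed, 5L),
                              beta = cfg$betaValidation)
  truth <- expr$truth
  truth$betaDiscovery <- cfg$betaDiscovery
  truth$betaValidation <- cfg$betaValidation
  truth$censoringRate <- cfg$censoringRate
  out <- list(se = expr$se, annotations = expr$annotations,
              clinicalDiscovery = clinDisc, clinicalValidation = clinVal,
              truth = truth)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeExpressionMatrix(out$se, file.path(outDir, "matrix.tsv"))
    writeTsv <- function(df, path) {
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, na = "NA")
    }
    writeTsv(out$annotations, file.path(outDir, "annotations.tsv"))
    writeTsv(clinDisc, file.path(outDir, "clinical_discovery.tsv"))
    writeTsv(clinVal, file.path(outDir, "clinical_validation.tsv"))
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      keep <- truth[c("markerGene", "targetGene", "planted", "piLow", "eps",
                      "bimodalGenes", "deGenes", "deShift", "trueThreshold",
                      "betaDiscovery", "betaValidation", "censoringRate")]
      jsonlite::write_json(keep, file.path(outDir, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  out
}
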