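## Asymmetric Boolean-implication statistics between binarized gene pairs.
## For a relation "X-a implies Y-b" (a, b in {low, high}) the 2x2 low/high
## contingency table of the pair should have a sparse (X = a, Y = not b)
## quadrant relative to independence. The statistic S measures the deficit
## of that quadrant in units of its Poisson-scale spread, and the error
## rate is the average conditional leak into it.

IMPLICATION_RELATIONS <- c("low->high", "low->low", "high->low", "high->high")

## sparse quadrant (X side, Y side) per relation; "L"/"H" call of each gene
sparseQuadrant <- function(relation) {
  switch(relation,
         "low->high"  = c("L", "L"),
         "low->low"   = c("L", "H"),
         "high->low"  = c("H", "H"),
         "high->high" = c("H", "L"))
}

#' Quadrant counts of a binarized gene pair
#'
#' Cross-tabulates two call vectors over their shared sample universe. A
#' sample contributes iff both calls are LOW or HIGH; INTERMEDIATE and
#' MISSING calls are excluded.
#'
#' @param callsX,callsY call vectors over the same samples: factors or
#'   character vectors with values in LOW/INTERMEDIATE/HIGH/MISSING, or
#'   integer codes (0/1/2/NA). If both are named, names must match as sets.
#' @return object of class \code{QuadrantCounts}: list with \code{nLL},
#'   \code{nLH}, \code{nHL}, \code{nHH} (X-call then Y-call), \code{n} and
#'   \code{nExcluded}.
#' @export
quadrantCounts <- function(callsX, callsY) {
  cx <- asCallCodes(callsX)
  cy <- asCallCodes(callsY)
  stopIfNot(length(cx) == length(cy),
            "call vectors differ in length (%d vs %d)", length(cx), length(cy))
  if (!is.null(names(cx)) && !is.null(names(cy))) {
    stopIfNot(setequal(names(cx), names(cy)),
              "call vectors cover different sample sets")
    cy <- cy[names(cx)]
  }
  use <- !is.na(cx) & !is.na(cy) & cx != 1L & cy != 1L
  xl <- cx[use] == 0L
  yl <- cy[use] == 0L
  out <- list(nLL = sum(xl & yl), nLH = sum(xl & !yl),
              nHL = sum(!xl & yl), nHH = sum(!xl & !yl),
              n = sum(use), nExcluded = sum(!use))
  class(out) <- "QuadrantCounts"
  out
}

asCallCodes <- function(calls) {
  if (is.numeric(calls)) {
    codes <- as.integer(calls)
    stopIfNot(all(codes %in% 0:2 | is.na(codes)),
              "integer call codes must be 0/1/2 or NA")
    return(codes)
  }
  lab <- as.character(calls)
  stopIfNot(all(lab %in% CALL_LEVELS | is.na(lab)),
            "calls must be in {%s}", paste(CALL_LEVELS, collapse = ", "))
  codes <- c(LOW = 0L, INTERMEDIATE = 1L, HIGH = 2L, MISSING = NA_integer_)[lab]
  names(codes) <- names(calls)
  codes
}

#' @export
print.QuadrantCounts <- function(x, ...) {
  cat(sprintf("QuadrantCounts (X,Y): LL %d  LH %d  HL %d  HH %d  (n = %d, excluded %d)\n",
              x$nLL, x$nLH, x$nHL, x$nHH, x$n, x$nExcluded))
  invisible(x)
}

#' Sparse-quadrant implication statistic
#'
#' For relation \code{"low->high"} the sparse quadrant is (X-low, Y-low):
#' with observed count \eqn{o = n_{LL}}, expectation under independence
#' \eqn{e = (n_{LL}+n_{LH})(n_{LL}+n_{HL})/n}, the statistic is
#' \eqn{S = (e - o)/\sqrt{e}} and the error rate is the mean conditional
#' leak \eqn{err = (o/(n_{LL}+n_{LH}) + o/(n_{LL}+n_{HL}))/2}. The other
#' three relations permute quadrants analogously. The relation passes iff
#' \eqn{S > s_{min}} and \eqn{err < err_{max}}.
#'
#' A zero row or column margin for the tested quadrant makes the statistic
#' not evaluable: \code{passes = FALSE}, statistic \code{NA}, logged.
#'
#' @param counts a \code{QuadrantCounts}.
#' @param relation one of \code{"low->high"}, \code{"low->low"},
#'   \code{"high->low"}, \code{"high->high"}.
#' @param sMin minimum statistic (default 3.0).
#' @param errMax maximum error rate (default 0.1).
#' @return object of class \code{ImplicationStat}: list with
#'   \code{relation}, \code{sparse} (observed sparse count), \code{expected},
#'   \code{statistic}, \code{errorRate}, \code{passes}, \code{evaluable}.
#' @export
implicationStatistic <- function(counts, relation = "low->high",
                                 sMin = 3.0, errMax = 0.1) {
  relation <- match.arg(relation, IMPLICATION_RELATIONS)
  q <- sparseQuadrant(relation)
  cnt <- matrix(c(counts$nLL, counts$nLH, counts$nHL, counts$nHH), 2L, 2L,
                byrow = TRUE, dimnames = list(c("L", "H"), c("L", "H")))
  o <- cnt[q[1L], q[2L]]
  rowM <- sum(cnt[q[1L], ])
  colM <- sum(cnt[, q[2L]])
  n <- counts$n
  out <- list(relation = relation, sparse = o, expected = NA_real_,
              statistic = NA_real_, errorRate = NA_real_,
              passes = FALSE, evaluable = FALSE,
              sMin = sMin, errMax = errMax)
  if (n == 0L || rowM == 0L || colM == 0L) {
    bsLog("implicationStatistic: zero margin for the %s sparse quadrant; not evaluable",
          relation)
    class(out) <- "ImplicationStat"
    return(out)
  }
  e <- rowM * colM / n
  out$expected <- e
  out$statistic <- (e - o) / sqrt(e)
  out$errorRate <- (o / rowM + o / colM) / 2
  out$passes <- (out$statistic > sMin) && (out$errorRate < errMax)
  out$evaluable <- TRUE
  class(out) <- "ImplicationStat"
  out
}

#' @export
print.ImplicationStat <- function(x, ...) {
  if (!x$evaluable) {
    cat(sprintf("ImplicationStat [%s]: not evaluable (zero margin)\n",
                x$relation))
  } else {
    cat(sprintf("ImplicationStat [%s]: S = %.3f, err = %.3f (o = %d, e = %.2f) -> %s\n",
                x$relation, x$statistic, x$errorRate, x$sparse, x$expected,
                if (x$passes) "PASS" else "no pass"))
  }
  invisible(x)
}

## Vectorized scan of every gene against a fixed target call vector.
## callsMat: integer-code matrix (genes x samples); targetCalls: codes.
## Returns per-gene quadrant counts and statistics as plain vectors.
implicationScan <- function(callsMat, targetCalls, relation,
                            sMin, errMax, minN) {
  xl <- callsMat == 0L; xl[is.na(xl)] <- FALSE
  xh <- callsMat == 2L; xh[is.na(xh)] <- FALSE
  yl <- as.numeric(!is.na(targetCalls) & targetCalls == 0L)
  yh <- as.numeric(!is.na(targetCalls) & targetCalls == 2L)
  nLL <- drop(xl %*% yl); nLH <- drop(xl %*% yh)
  nHL <- drop(xh %*% yl); nHH <- drop(xh %*% yh)
  n <- nLL + nLH + nHL + nHH
  q <- sparseQuadrant(relation)
  o <- if (q[1L] == "L") { if (q[2L] == "L") nLL else nLH
       } else             { if (q[2L] == "L") nHL else nHH }
  rowM <- if (q[1L] == "L") nLL + nLH else nHL + nHH
  colM <- if (q[2L] == "L") nLL + nHL else nLH + nHH
  evaluable <- n > 0 & rowM > 0 & colM > 0
  e <- S <- err <- rep(NA_real_, length(n))
  e[evaluable] <- (rowM * colM / n)[evaluable]
  S[evaluable] <- ((e - o) / sqrt(e))[evaluable]
  err[evaluable] <- ((o / rowM + o / colM) / 2)[evaluable]
  passes <- !is.na(S) & S > sMin & !is.na(err) & err < errMax & n >= minN
  list(nLL = nLL, nLH = nLH, nHL = nHL, nHH = nHH, n = n,
       expected = e, statistic = S, errorRate = err,
       evaluable = evaluable, passes = passes)
}

resolvePopulation <- function(callset, population) {
  if (is.null(population)) return(colnames(callset))
  if (is.logical(population)) {
    stopIfNot(length(population) == ncol(callset),
              "logical population filter has wrong length")
    return(colnames(callset)[population])
  }
  missingIds <- setdiff(population, colnames(callset))
  stopIfNot(length(missingIds) == 0L, "population sample(s) not found: %s",
            paste(utils::head(missingIds, 5L), collapse = ", "))
  population
}

#' Genome-wide search for implication partners of a target gene
#'
#' Tests every gene X (other than the target Y) for the relation
#' \code{X-<a> implies Y-<b>} over the selected sample population, using
#' only samples where both genes have a LOW or HIGH call. Genes whose
#' usable pair count falls below \code{minN} are dropped (logged).
#'
#' @param callset a \linkS4class{BooleanCallSet}.
#' @param target target gene id (e.g. the mesenchymal marker VIM).
#' @param relation implication relation, default \code{"low->high"}
#'   ("X-low implies Y-high").
#' @param population sample subset: \code{NULL} (all samples), a character
#'   vector of sample ids, or a logical vector over columns. Support
#'   fractions are relative to this population.
#' @param sMin,errMax pass thresholds (see
#'   \code{\link{implicationStatistic}}).
#' @param minN minimum usable pair count (default 20).
#' @return data.frame sorted by statistic descending: one row per tested
#'   gene with quadrant counts, \code{expected}, \code{statistic},
#'   \code{errorRate}, \code{supportFraction} (= n / population size) and
#'   \code{passes}.
#' @export
searchPartners <- function(callset, target, relation = "low->high",
                           population = NULL, sMin = 3.0, errMax = 0.1,
                           minN = 20L) {
  relation <- match.arg(relation, IMPLICATION_RELATIONS)
  stopIfNot(target %in% rownames(callset),
            "target gene '%s' not in call set", target)
  pop <- resolvePopulation(callset, population)
  codes <- SummarizedExperiment::assay(callset, "calls")[, pop, drop = FALSE]
  tcalls <- codes[target, ]
  others <- setdiff(rownames(codes), target)
  if (length(others) == 0L) {
    return(emptyImplicationFrame(relation))
  }
  sc <- implicationScan(codes[others, , drop = FALSE], tcalls, relation,
                        sMin, errMax, minN)
  keep <- sc$n >= minN
  if (any(!keep)) {
    bsLog("searchPartners: %d gene(s) dropped (usable pair count < %d)",
          sum(!keep), minN)
  }
  out <- data.frame(
    gene = others, target = target, relation = relation,
    nLL = sc$nLL, nLH = sc$nLH, nHL = sc$nHL, nHH = sc$nHH, n = sc$n,
    expected = sc$expected, statistic = sc$statistic,
    errorRate = sc$errorRate,
    supportFraction = sc$n / length(pop),
    evaluable = sc$evaluable, passes = sc$passes,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  out <- out[order(-out$statistic, out$gene, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

emptyImplicationFrame <- function(relation) {
  data.frame(gene = character(), target = character(),
             relation = character(), nLL = numeric(), nLH = numeric(),
             nHL = numeric(), nHH = numeric(), n = numeric(),
             expected = numeric(), statistic = numeric(),
             errorRate = numeric(), supportFraction = numeric(),
             evaluable = logical(), passes = logical(),
             stringsAsFactors = FALSE)
}

#' Permutation false-discovery rate for the partner search
#'
#' Each permutation independently shuffles every non-target gene's calls
#' across samples (destroying pairwise association while preserving each
#' gene's call composition) and re-counts passing implications. The FDR
#' estimate for a threshold configuration is the mean passing count over
#' permutations divided by the observed passing count, reported as 1.0 when
#' the observed count is zero.
#'
#' @inheritParams searchPartners
#' @param sMin,errMax pass thresholds; vectors of equal length evaluate
#'   several configurations on one set of permutations.
#' @param nPerm number of permutations (>= 1).
#' @param seed integer seed; fixing it makes the estimate bit-reproducible.
#' @return data.frame with one row per threshold configuration:
#'   \code{sMin}, \code{errMax}, \code{observed}, \code{meanNull},
#'   \code{fdr}.
#' @export
estimateFDR <- function(callset, target, relation = "low->high",
                        population = NULL, sMin = 3.0, errMax = 0.1,
                        minN = 20L, nPerm = 100L, seed = 1L) {
  relation <- match.arg(relation, IMPLICATION_RELATIONS)
  stopIfNot(nPerm >= 1L, "nPerm must be >= 1")
  stopIfNot(target %in% rownames(callset),
            "target gene '%s' not in call set", target)
  cfg <- data.frame(sMin = sMin, errMax = errMax)   # recycles to max length
  pop <- resolvePopulation(callset, population)
  codes <- SummarizedExperiment::assay(callset, "calls")[, pop, drop = FALSE]
  tcalls <- codes[target, ]
  others <- setdiff(rownames(codes), target)
  mat <- codes[others, , drop = FALSE]
  nPass <- function(m) {
    sc <- implicationScan(m, tcalls, relation, sMin = -Inf, errMax = Inf,
                          minN = 0L)
    ok <- sc$n >= minN & sc$evaluable
    vapply(seq_len(nrow(cfg)), function(i) {
      sum(ok & !is.na(sc$statistic) & sc$statistic > cfg$sMin[i] &
            sc$errorRate < cfg$errMax[i])
    }, numeric(1L))
  }
  observed <- nPass(mat)
  ns <- ncol(mat)
  set.seed(seed)
  nullCounts <- matrix(0, nrow = nPerm, ncol = nrow(cfg))
  for (p in seq_len(nPerm)) {
    perm <- mat
    for (i in seq_len(nrow(mat))) perm[i, ] <- mat[i, sample.int(ns)]
    nullCounts[p, ] <- nPass(perm)
  }
  meanNull <- colMeans(nullCounts)
  fdr <- ifelse(observed == 0, 1.0, meanNull / observed)
  data.frame(sMin = cfg$sMin, errMax = cfg$errMax, observed = observed,
             meanNull = meanNull, fdr = fdr)
}
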