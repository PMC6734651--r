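## Step-function binarization of expression values. Each gene's sorted
## values are fitted with a one-step function (two constant segments); the
## step location defines a high/low cutoff placed at the midpoint of the two
## segment means, with a configurable intermediate margin around it.

## Vectorized core: given sorted values, the step SSE for every breakpoint
## i in 1..n-1 via prefix sums. Returns the fit at the SSE-minimizing
## breakpoint; ties broken by the smallest index.
stepCore <- function(sorted) {
  n <- length(sorted)
  cs <- cumsum(sorted)
  tot <- cs[n]
  ssq <- sum(sorted^2)
  i <- seq_len(n - 1L)
  muL <- cs[i] / i
  muR <- (tot - cs[i]) / (n - i)
  sse <- ssq - i * muL^2 - (n - i) * muR^2
  sse <- pmax(sse, 0)                       # clamp floating-point negatives
  best <- which(sse <= min(sse) + 1e-9 * max(1, ssq))[1L]
  sseFlat <- max(ssq - tot^2 / n, 0)
  list(breakpoint = best, muL = muL[best], muR = muR[best],
       threshold = (muL[best] + muR[best]) / 2,
       sseStep = sse[best], sseFlat = sseFlat)
}

#' Fit a one-step threshold to a gene's expression values
#'
#' Sorts the values ascending and finds the breakpoint \eqn{i^*} (1-based
#' count of left-segment samples, \eqn{1 \le i^* \le n-1}) minimizing the
#' within-segment sum of squares
#' \eqn{\sum_{left}(x-\mu_L)^2 + \sum_{right}(x-\mu_R)^2}. The threshold is
#' the midpoint \eqn{(\mu_L+\mu_R)/2}. Ties in SSE are broken by the
#' smallest breakpoint. The F statistic compares the step fit against the
#' flat (grand-mean) fit: \eqn{F = (SSE_{flat}-SSE_{step}) / (SSE_{step}/(n-2))}.
#'
#' @param values numeric vector of at least 4 finite log2 values (missing
#'   values must be removed by the caller).
#' @return object of class \code{StepFit}: list with \code{breakpoint},
#'   \code{muL}, \code{muR}, \code{threshold}, \code{sseStep},
#'   \code{sseFlat}, \code{fStat}, \code{degenerate} (TRUE iff
#'   \eqn{\mu_R - \mu_L = 0}) and \code{n}.
#' @examples
#' fitStepThreshold(c(0, 0, 0, 4, 4, 4))$threshold  # 2
#' @export
fitStepThreshold <- function(values) {
  stopIfNot(is.numeric(values), "values must be numeric")
  stopIfNot(all(is.finite(values)), "values must all be finite")
  n <- length(values)
  stopIfNot(n >= 4L, "need at least 4 values, got %d", n)
  fit <- stepCore(sort(values))
  fit$fStat <- if (fit$sseStep > 0) {
    (fit$sseFlat - fit$sseStep) / (fit$sseStep / (n - 2L))
  } else if (fit$sseFlat > 0) Inf else NA_real_
  fit$degenerate <- (fit$muR - fit$muL) == 0
  fit$n <- n
  class(fit) <- "StepFit"
  fit
}

#' @export
print.StepFit <- function(x, ...) {
  cat(sprintf(
    "StepFit: threshold %.4g (muL %.4g, muR %.4g, breakpoint %d/%d)%s\n",
    x$threshold, x$muL, x$muR, x$breakpoint, x$n,
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Classify samples as LOW / INTERMEDIATE / HIGH
#'
#' Applies the fitted threshold \eqn{t} with a symmetric margin \eqn{m}:
#' LOW iff \eqn{x < t - m}, HIGH iff \eqn{x > t + m}, INTERMEDIATE iff
#' \eqn{|x - t| \le m}, MISSING for missing values. A degenerate fit (no
#' step) yields INTERMEDIATE for every non-missing sample.
#'
#' @param values numeric vector (may contain \code{NA}).
#' @param fit a \code{StepFit} for the same gene.
#' @param margin non-negative margin in log2 units.
#' @return factor with levels LOW, INTERMEDIATE, HIGH, MISSING.
#' @export
classifySamples <- function(values, fit, margin = 0.5) {
  stopIfNot(is.numeric(margin) && length(margin) == 1L && margin >= 0,
            "margin must be a single non-negative number")
  codes <- classifyCodes(values, fit$threshold, margin, fit$degenerate)
  out <- codesToLabels(codes)
  names(out) <- names(values)
  out
}

classifyCodes <- function(values, threshold, margin, degenerate) {
  codes <- rep(NA_integer_, length(values))
  ok <- !is.na(values)
  if (degenerate) {
    codes[ok] <- 1L
  } else {
    codes[ok & values < threshold - margin] <- 0L
    codes[ok & values > threshold + margin] <- 2L
    codes[ok & abs(values - threshold) <= margin] <- 1L
  }
  codes
}

#' Threshold every gene of an expression matrix
#'
#' Runs \code{\link{fitStepThreshold}} on each gene's non-missing values and
#' classifies all samples with the given margin. Genes with fewer than 4
#' non-missing values are skipped with a logged count.
#'
#' @param se SummarizedExperiment with an \code{"exprs"} assay (or a numeric
#'   genes-by-samples matrix with dimnames).
#' @param margin intermediate-zone half-width in log2 units. The default
#'   0.5 suits Boolean-implication analysis; use 0 for patient-level
#'   subgrouping so that every patient is called high or low.
#' @return a \linkS4class{BooleanCallSet}.
#' @export
thresholdAllGenes <- function(se, margin = 0.5) {
  stopIfNot(is.numeric(margin) && length(margin) == 1L && margin >= 0,
            "margin must be a single non-negative number")
  m <- if (is.matrix(se)) se else SummarizedExperiment::assay(se, "exprs")
  nOk <- rowSums(!is.na(m))
  skip <- nOk < 4L
  if (any(skip)) {
    bsLog("thresholdAllGenes: %d gene(s) skipped (< 4 non-missing values)",
          sum(skip))
  }
  keep <- which(!skip)
  ng <- length(keep)
  calls <- matrix(NA_integer_, nrow = ng, ncol = ncol(m),
                  dimnames = list(rownames(m)[keep], colnames(m)))
  rd <- data.frame(breakpoint = integer(ng), muL = numeric(ng),
                   muR = numeric(ng), threshold = numeric(ng),
                   sseStep = numeric(ng), sseFlat = numeric(ng),
                   fStat = numeric(ng), degenerate = logical(ng),
                   nUsed = integer(ng))
  for (k in seq_len(ng)) {
    v <- m[keep[k], ]
    fit <- fitStepThreshold(v[!is.na(v)])
    rd[k, c("breakpoint", "muL", "muR", "threshold", "sseStep", "sseFlat",
            "fStat", "nUsed")] <-
      list(fit$breakpoint, fit$muL, fit$muR, fit$threshold, fit$sseStep,
           fit$sseFlat, fit$fStat, fit$n)
    rd$degenerate[k] <- fit$degenerate
    calls[k, ] <- classifyCodes(v, fit$threshold, margin, fit$degenerate)
  }
  cd <- if (is.matrix(se)) {
    S4Vectors::DataFrame(row.names = colnames(m))
  } else {
    SummarizedExperiment::colData(se)
  }
  methods::new(
    "BooleanCallSet",
    SummarizedExperiment::SummarizedExperiment(
      assays = list(exprs = m[keep, , drop = FALSE], calls = calls),
      rowData = rd, colData = cd,
      metadata = list(margin = margin)))
}
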