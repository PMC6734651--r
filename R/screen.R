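## Candidate-reduction filters applied after the implication search:
## population support, then differential expression of each surviving gene
## versus normal mucosa and versus inflammatory bowel disease tissue.

#' Filter implication results by population support
#'
#' Retains results whose \code{supportFraction} (fraction of the searched
#' population contributing usable LOW/HIGH pairs) is at least
#' \code{minFraction}; results identified from a smaller slice of the
#' population are dropped with a logged count.
#'
#' @param results data.frame from \code{\link{searchPartners}}.
#' @param minFraction minimum support fraction in [0, 1] (default 0.40).
#' @return the retained rows.
#' @export
supportFilter <- function(results, minFraction = 0.40) {
  stopIfNot(is.numeric(minFraction) && minFraction >= 0 && minFraction <= 1,
            "minFraction must be in [0, 1]")
  keep <- results$supportFraction >= minFraction
  bsLog("supportFilter: %d of %d result(s) removed (support fraction < %.2f)",
        sum(!keep), length(keep), minFraction)
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-gene differential expression between two sample groups
#'
#' Welch's two-sample t test on log2 values, gene by gene. The fold change
#' is \eqn{2^{|\Delta \bar x|}} so it is always >= 1 regardless of
#' direction. Genes with fewer than 3 non-missing values in either group
#' are skipped with a logged count.
#'
#' @param se SummarizedExperiment with an \code{"exprs"} assay or a numeric
#'   matrix.
#' @param samplesA,samplesB character vectors of sample ids (disjoint
#'   non-empty groups), e.g. CRC vs. normal mucosa.
#' @return data.frame: \code{gene}, \code{meanA}, \code{meanB},
#'   \code{log2FC} (= meanA - meanB), \code{foldChange}, \code{tStat},
#'   \code{df}, \code{pValue}.
#' @export
differentialExpression <- function(se, samplesA, samplesB) {
  m <- if (is.matrix(se)) se else SummarizedExperiment::assay(se, "exprs")
  stopIfNot(length(samplesA) > 0L && length(samplesB) > 0L,
            "both groups must be non-empty")
  badA <- setdiff(samplesA, colnames(m))
  badB <- setdiff(samplesB, colnames(m))
  stopIfNot(length(badA) == 0L && length(badB) == 0L,
            "unknown sample id(s): %s",
            paste(utils::head(c(badA, badB), 5L), collapse = ", "))
  a <- m[, samplesA, drop = FALSE]
  b <- m[, samplesB, drop = FALSE]
  nA <- rowSums(!is.na(a)); nB <- rowSums(!is.na(b))
  keep <- nA >= 3L & nB >= 3L
  if (any(!keep)) {
    bsLog("differentialExpression: %d gene(s) skipped (< 3 non-missing values in a group)",
          sum(!keep))
  }
  a <- a[keep, , drop = FALSE]; b <- b[keep, , drop = FALSE]
  nA <- nA[keep]; nB <- nB[keep]
  mA <- rowMeans(a, na.rm = TRUE); mB <- rowMeans(b, na.rm = TRUE)
  vA <- apply(a, 1L, stats::var, na.rm = TRUE)
  vB <- apply(b, 1L, stats::var, na.rm = TRUE)
  seD <- sqrt(vA / nA + vB / nB)
  t <- (mA - mB) / seD
  df <- seD^4 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  p <- 2 * stats::pt(-abs(t), df)
  ## zero-variance, zero-difference genes: t = 0/0; report no evidence
  flat <- !is.na(seD) & seD == 0 & mA == mB
  t[flat] <- 0; p[flat] <- 1; df[flat] <- nA[flat] + nB[flat] - 2
  lfc <- mA - mB
  data.frame(gene = rownames(a), meanA = mA, meanB = mB, log2FC = lfc,
             foldChange = 2^abs(lfc), tStat = t, df = df, pValue = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Screen implication hits into biomarker candidates
#'
#' A gene is a candidate iff it passes the support filter and is
#' differentially expressed with fold change strictly greater than
#' \code{fcMin} at p strictly below \code{pMax} in \emph{both} comparisons
#' (vs. normal and vs. IBD). Every filter flag is carried in the output for
#' audit. Genes present in \code{results} but absent from either DE table
#' are flagged not-evaluable, excluded and logged. No multiple-testing
#' correction is applied inside the DE filter; FDR control lives in the
#' implication stage.
#'
#' @param results implication results (data.frame from
#'   \code{\link{searchPartners}}, typically pre-filtered to passing rows).
#' @param deNormal,deIbd DE tables from
#'   \code{\link{differentialExpression}}: candidate population vs. normal
#'   mucosa and vs. IBD tissue.
#' @param minFraction support-fraction cutoff (default 0.40).
#' @param fcMin fold-change cutoff, strict (default 2.0).
#' @param pMax p-value cutoff, strict (default 0.001).
#' @return data.frame with one row per evaluable gene: implication
#'   statistics, both DE results, individual pass flags and
#'   \code{candidate}.
#' @export
screenCandidates <- function(results, deNormal, deIbd,
                             minFraction = 0.40, fcMin = 2.0, pMax = 0.001) {
  iN <- match(results$gene, deNormal$gene)
  iI <- match(results$gene, deIbd$gene)
  notEval <- is.na(iN) | is.na(iI)
  if (any(notEval)) {
    bsLog("screenCandidates: %d gene(s) not evaluable (absent from a DE table); excluded",
          sum(notEval))
  }
  keep <- !notEval
  r <- results[keep, , drop = FALSE]
  dn <- deNormal[iN[keep], , drop = FALSE]
  di <- deIbd[iI[keep], , drop = FALSE]
  out <- data.frame(
    gene = r$gene,
    statistic = r$statistic, errorRate = r$errorRate,
    supportFraction = r$supportFraction,
    implicationPasses = r$passes,
    fcNormal = dn$foldChange, pNormal = dn$pValue,
    fcIbd = di$foldChange, pIbd = di$pValue,
    passSupport = r$supportFraction >= minFraction,
    passDeNormal = dn$foldChange > fcMin & dn$pValue < pMax,
    passDeIbd = di$foldChange > fcMin & di$pValue < pMax,
    stringsAsFactors = FALSE
  )
  out$candidate <- out$passSupport & out$passDeNormal & out$passDeIbd
  out <- out[order(-out$candidate, -out$statistic, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
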