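#' BooleanCallSet: expression values plus per-gene step fits and Boolean calls
#'
#' A \linkS4class{SummarizedExperiment} subclass holding a log2 expression
#' assay (\code{"exprs"}), an integer call assay (\code{"calls"}: 0 = LOW,
#' 1 = INTERMEDIATE, 2 = HIGH, \code{NA} = missing), and the per-gene step
#' fits in \code{rowData} (columns \code{breakpoint}, \code{muL}, \code{muR},
#' \code{threshold}, \code{sseStep}, \code{sseFlat}, \code{fStat},
#' \code{degenerate}, \code{nUsed}). The intermediate-zone margin (log2
#' units) used to produce the calls is stored in \code{metadata()$margin}.
#'
#' Construct with \code{\link{thresholdAllGenes}}; access calls with
#' \code{\link{booleanCalls}} and fits with \code{\link{stepFits}}.
#'
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @exportClass BooleanCallSet
setClass("BooleanCallSet", contains = "SummarizedExperiment")

setValidity("BooleanCallSet", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("exprs", "calls") %in% an)) {
    msg <- c(msg, "assays must include 'exprs' and 'calls'")
  } else {
    calls <- SummarizedExperiment::assay(object, "calls")
    bad <- calls[!is.na(calls)]
    if (length(bad) && !all(bad %in% 0:2)) {
      msg <- c(msg, "call codes must be 0 (LOW), 1 (INTERMEDIATE) or 2 (HIGH)")
    }
  }
  need <- c("breakpoint", "muL", "muR", "threshold", "sseStep", "sseFlat",
            "fStat", "degenerate", "nUsed")
  if (!all(need %in% colnames(SummarizedExperiment::rowData(object)))) {
    msg <- c(msg, paste("rowData must carry step-fit columns:",
                        paste(need, collapse = ", ")))
  }
  m <- S4Vectors::metadata(object)$margin
  if (is.null(m) || !is.numeric(m) || length(m) != 1L || m < 0) {
    msg <- c(msg, "metadata()$margin must be a single non-negative number")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn BooleanCallSet compact display
#' @param object a \code{BooleanCallSet}
#' @export
setMethod("show", "BooleanCallSet", function(object) {
  cat("BooleanCallSet with", nrow(object), "genes x", ncol(object),
      "samples\n")
  cat("  margin:", S4Vectors::metadata(object)$margin, "log2 units\n")
  rd <- SummarizedExperiment::rowData(object)
  cat("  degenerate fits:", sum(rd$degenerate), "\n")
  invisible(NULL)
})

#' Call codes used in the calls assay
#'
#' @return named integer vector mapping call labels to assay codes.
#' @export
callCodes <- function() c(LOW = 0L, INTERMEDIATE = 1L, HIGH = 2L)

CALL_LEVELS <- c("LOW", "INTERMEDIATE", "HIGH", "MISSING")

codesToLabels <- function(codes) {
  lab <- CALL_LEVELS[ifelse(is.na(codes), 4L, codes + 1L)]
  out <- factor(lab, levels = CALL_LEVELS)
  if (is.matrix(codes)) {
    out <- matrix(as.character(out), nrow = nrow(codes),
                  dimnames = dimnames(codes))
  } else {
    names(out) <- names(codes)
  }
  out
}

#' @rdname booleanCalls
#' @export
setGeneric("booleanCalls", function(x, labels = TRUE) {
  standardGeneric("booleanCalls")
})

#' Extract Boolean expression calls
#'
#' @param x a \code{BooleanCallSet}
#' @param labels return a character matrix with values in
#'   \code{LOW/INTERMEDIATE/HIGH/MISSING} (default); \code{FALSE} returns the
#'   raw integer codes (\code{NA} = missing).
#' @return genes-by-samples matrix of calls.
#' @export
setMethod("booleanCalls", "BooleanCallSet", function(x, labels = TRUE) {
  codes <- SummarizedExperiment::assay(x, "calls")
  if (labels) codesToLabels(codes) else codes
})

#' @rdname stepFits
#' @export
setGeneric("stepFits", function(x) standardGeneric("stepFits"))

#' Extract per-gene step fits
#'
#' @param x a \code{BooleanCallSet}
#' @return data.frame with one row per gene: breakpoint index, segment means,
#'   threshold, step and flat sums of squares, F statistic, degeneracy flag
#'   and number of non-missing values used.
#' @export
setMethod("stepFits", "BooleanCallSet", function(x) {
  df <- as.data.frame(SummarizedExperiment::rowData(x))
  df$gene <- rownames(x)
  df[, c("gene", "breakpoint", "muL", "muR", "threshold", "sseStep",
         "sseFlat", "fStat", "degenerate", "nUsed")]
})

#' @rdname callMargin
#' @export
setGeneric("callMargin", function(x) standardGeneric("callMargin"))

#' Intermediate-zone margin of a BooleanCallSet
#'
#' @param x a \code{BooleanCallSet}
#' @return the margin in log2 units.
#' @export
setMethod("callMargin", "BooleanCallSet", function(x) {
  S4Vectors::metadata(x)$margin
})
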