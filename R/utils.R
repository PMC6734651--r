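#' @keywords internal
#' @import methods
"_PACKAGE"

## Filter/exclusion logging. Every rule that drops rows, genes or samples
## reports the count removed and the rule applied; silenced via
## options(BoolScreen.verbose = FALSE).
bsLog <- function(fmt, ...) {
  if (isTRUE(getOption("BoolScreen.verbose", TRUE))) {
    message("[BoolScreen] ", sprintf(fmt, ...))
  }
  invisible(NULL)
}

## Derive a per-unit sub-seed from a master seed and an index so that adding
## units (genes, patients) never perturbs the streams of existing ones.
## Kept below 2^31 - 1 (R integers are 32-bit).
subSeed <- function(seed, index) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(index)) %% 2147483629)
}

stopIfNot <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
}
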