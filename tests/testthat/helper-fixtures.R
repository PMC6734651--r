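options(BoolScreen.verbose = FALSE)

## write a TSV fixture from header + rows
writeTsv <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

## tiny expression SummarizedExperiment built in code
makeSE <- function(m) {
  SummarizedExperiment::SummarizedExperiment(assays = list(exprs = m))
}

## independent brute-force step-fit oracle: enumerate every breakpoint and
## accumulate the two segment SSEs directly
bruteStepFit <- function(values) {
  v <- sort(values)
  n <- length(v)
  best <- list(sse = Inf, i = NA_integer_, muL = NA_real_, muR = NA_real_)
  for (i in seq_len(n - 1L)) {
    left <- v[seq_len(i)]
    right <- v[(i + 1L):n]
    sse <- sum((left - mean(left))^2) + sum((right - mean(right))^2)
    if (sse < best$sse - 1e-12) {
      best <- list(sse = sse, i = i, muL = mean(left), muR = mean(right))
    }
  }
  best
}

## enumerate all sorted value vectors of given length over an alphabet
## (combinations with repetition; the fit is permutation invariant)
sortedVectors <- function(len, alphabet) {
  idx <- utils::combn(length(alphabet) + len - 1L, len)
  apply(idx, 2L, function(k) alphabet[k - seq_len(len) + 1L],
        simplify = FALSE)
}

## small fast study config for unit tests (overridable defaults)
smallConfig <- function(...) {
  args <- utils::modifyList(
    list(nCRC = 200L, nPolyp = 10L, nIBD = 40L, nNormal = 40L,
         nGenes = 60L, nBimodal = 10L, nDE = 2L,
         nDiscovery = 150L, nValidation = 120L),
    list(...))
  do.call(studyConfig, args)
}

## re-enable filter logging inside a test that asserts on messages
localVerbose <- function(env = parent.frame()) {
  withr::local_options(list(BoolScreen.verbose = TRUE), .local_envir = env)
}

crcSamples <- function(se) {
  colnames(se)[SummarizedExperiment::colData(se)$tissue_class == "CRC"]
}
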