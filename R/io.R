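## Readers/writers for the three TSV tables the pipeline consumes, plus
## cohort merging. One dialect only: tab-separated, single header row,
## "NA" or an empty cell marks a missing value on read, "NA" on write.
## Gene symbols are opaque keys; no alias resolution, no renormalization
## (matrices are taken as already comparable across cohorts).

TISSUE_CLASSES <- c("CRC", "polyp", "IBD", "normal")

#' Read a log2 expression matrix from TSV
#'
#' Expects a single header row of sample ids, first column gene ids, and
#' tab-separated log2 values. \code{"NA"} or an empty cell denotes a missing
#' value. Row and column order are preserved.
#'
#' @param path path to a TSV file.
#' @return a \link[SummarizedExperiment]{SummarizedExperiment} with one
#'   assay \code{"exprs"} (genes x samples, \code{NA} = missing).
#' @export
readExpressionMatrix <- function(path) {
  stopIfNot(file.exists(path), "file not found: %s", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "")
  stopIfNot(ncol(raw) >= 2L, "expression file needs gene ids plus >= 1 sample")
  genes <- raw[[1L]]
  samples <- colnames(raw)[-1L]
  dup <- unique(genes[duplicated(genes)])
  stopIfNot(length(dup) == 0L, "duplicate gene id(s): %s",
            paste(dup, collapse = ", "))
  dup <- unique(samples[duplicated(samples)])
  stopIfNot(length(dup) == 0L, "duplicate sample id(s): %s",
            paste(dup, collapse = ", "))
  vals <- matrix(NA_real_, nrow = length(genes), ncol = length(samples),
                 dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    cell <- raw[[j + 1L]]
    isMissing <- cell == "" | cell == "NA"
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!isMissing & is.na(num))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                   cell[bad[1L]], genes[bad[1L]], samples[j]), call. = FALSE)
    }
    num[isMissing] <- NA_real_
    vals[, j] <- num
  }
  nonFinite <- which(!is.na(vals) & !is.finite(vals))
  stopIfNot(length(nonFinite) == 0L, "non-finite value(s) in expression matrix")
  SummarizedExperiment::SummarizedExperiment(assays = list(exprs = vals))
}

#' Write an expression matrix to TSV
#'
#' Inverse of \code{\link{readExpressionMatrix}}: missing entries are written
#' as \code{"NA"}; values are printed with 17 significant digits so that a
#' write/read round trip reproduces them bit-identically.
#'
#' @param x a SummarizedExperiment with an \code{"exprs"} assay, or a numeric
#'   matrix with dimnames.
#' @param path output path.
#' @export
writeExpressionMatrix <- function(x, path) {
  m <- if (is.matrix(x)) x else SummarizedExperiment::assay(x, "exprs")
  stopIfNot(!is.null(rownames(m)) && !is.null(colnames(m)),
            "matrix must carry gene and sample ids as dimnames")
  chr <- matrix(sprintf("%.17g", m), nrow = nrow(m))
  chr[is.na(m)] <- "NA"
  lines <- c(paste(c("gene_id", colnames(m)), collapse = "\t"),
             paste(rownames(m), apply(chr, 1L, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample annotation table
#'
#' Tab-separated, one row per sample. Requires columns \code{sample_id} and
#' \code{tissue_class}; the molecular columns \code{msi}, \code{kras},
#' \code{braf}, \code{tp53} and \code{cohort_id} are optional and filled with
#' \code{"unknown"} (cohort: \code{"cohort1"}) when absent. Unrecognized
#' categories in the molecular columns map to \code{"unknown"}.
#'
#' @param path path to a TSV file.
#' @return data.frame keyed by \code{sample_id}.
#' @export
readAnnotations <- function(path) {
  stopIfNot(file.exists(path), "file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, quote = "")
  need <- c("sample_id", "tissue_class")
  missingCols <- setdiff(need, colnames(df))
  stopIfNot(length(missingCols) == 0L, "annotation table lacks column(s): %s",
            paste(missingCols, collapse = ", "))
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  stopIfNot(length(dup) == 0L, "duplicated sample_id(s): %s",
            paste(dup, collapse = ", "))
  bad <- setdiff(unique(df$tissue_class), TISSUE_CLASSES)
  stopIfNot(length(bad) == 0L,
            "tissue_class outside {%s}: %s",
            paste(TISSUE_CLASSES, collapse = ", "), paste(bad, collapse = ", "))
  enum3 <- function(col, levels) {
    if (!col %in% colnames(df)) return(rep("unknown", nrow(df)))
    v <- df[[col]]
    v[!(v %in% levels)] <- "unknown"
    v
  }
  out <- data.frame(
    sample_id = df$sample_id,
    tissue_class = df$tissue_class,
    msi = enum3("msi", c("MSI", "MSS")),
    kras = enum3("kras", c("mutant", "wildtype")),
    braf = enum3("braf", c("mutant", "wildtype")),
    tp53 = enum3("tp53", c("mutant", "wildtype")),
    cohort_id = if ("cohort_id" %in% colnames(df)) df$cohort_id else "cohort1",
    stringsAsFactors = FALSE
  )
  rownames(out) <- out$sample_id
  out
}

#' Attach sample annotations to an expression container
#'
#' Matches annotations to the object's samples by \code{sample_id}; samples
#' without an annotation row get \code{"unknown"} fields.
#'
#' @param se SummarizedExperiment (or BooleanCallSet).
#' @param ann annotation data.frame from \code{\link{readAnnotations}}.
#' @return \code{se} with populated \code{colData}.
#' @export
attachAnnotations <- function(se, ann) {
  idx <- match(colnames(se), ann$sample_id)
  nMiss <- sum(is.na(idx))
  if (nMiss > 0L) {
    bsLog("attachAnnotations: %d sample(s) without annotation row; fields set to 'unknown'",
          nMiss)
  }
  filled <- ann[idx, , drop = FALSE]
  filled$sample_id <- colnames(se)
  for (col in c("tissue_class", "msi", "kras", "braf", "tp53", "cohort_id")) {
    filled[[col]][is.na(filled[[col]])] <- "unknown"
  }
  rownames(filled) <- colnames(se)
  SummarizedExperiment::colData(se) <- S4Vectors::DataFrame(filled)
  se
}

CLINICAL_REQUIRED <- c("patient_id", "dfs_months", "dfs_event", "stage",
                       "age", "sex")

#' Read a clinical table
#'
#' Tab-separated with one header row. Required columns: \code{patient_id},
#' \code{dfs_months}, \code{dfs_event}, \code{stage} (I/II/III), \code{age},
#' \code{sex} (F/M). Optional: \code{dss_months}, \code{dss_event},
#' \code{location}, \code{grade}, \code{chemo}, \code{cea}, \code{ca199}.
#' Rows with non-positive survival times are rejected with a logged count;
#' a blank \code{chemo} cell becomes \code{"missing"} (the baseline table
#' shows an explicit Missing row).
#'
#' @param path path to a TSV file.
#' @return data.frame, one row per retained patient; \code{stage} is an
#'   ordered factor I < II < III.
#' @export
readClinicalTable <- function(path) {
  stopIfNot(file.exists(path), "file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, quote = "")
  missingCols <- setdiff(CLINICAL_REQUIRED, colnames(df))
  stopIfNot(length(missingCols) == 0L, "clinical table lacks column(s): %s",
            paste(missingCols, collapse = ", "))
  num <- function(col) suppressWarnings(as.numeric(
    ifelse(df[[col]] %in% c("", "NA"), NA, df[[col]])))
  out <- data.frame(
    patient_id = df$patient_id,
    dfs_months = num("dfs_months"),
    dfs_event = as.integer(num("dfs_event")),
    stage = factor(df$stage, levels = c("I", "II", "III"), ordered = TRUE),
    age = num("age"),
    sex = df$sex,
    stringsAsFactors = FALSE
  )
  for (col in c("dss_months", "dss_event", "cea", "ca199")) {
    if (col %in% colnames(df)) out[[col]] <- num(col)
  }
  if ("dss_event" %in% colnames(out)) {
    out$dss_event <- as.integer(out$dss_event)
  }
  out$location <- if ("location" %in% colnames(df)) {
    ifelse(df$location %in% c("colon", "rectum"), df$location, "unknown")
  } else "unknown"
  out$grade <- if ("grade" %in% colnames(df)) {
    ifelse(df$grade %in% c("well", "moderate", "poor"), df$grade, "unknown")
  } else "unknown"
  out$chemo <- if ("chemo" %in% colnames(df)) {
    ifelse(df$chemo %in% c("yes", "no"), df$chemo, "missing")
  } else "missing"
  stopIfNot(all(out$dfs_event %in% c(0L, 1L), na.rm = TRUE),
            "dfs_event must be 0/1")
  bad <- !is.na(out$dfs_months) & out$dfs_months <= 0
  bad <- bad | is.na(out$dfs_months)
  if (any(bad)) {
    bsLog("readClinicalTable: %d row(s) rejected (non-positive or missing dfs_months)",
          sum(bad))
    out <- out[!bad, , drop = FALSE]
  }
  rownames(out) <- out$patient_id
  out
}

#' Merge expression cohorts
#'
#' Column-binds cohorts with disjoint sample sets. The merged gene set is the
#' union of the input gene sets; entries for genes absent from a source
#' cohort are missing. No cross-cohort renormalization is performed: inputs
#' are assumed already comparable (e.g. single-sample normalized upstream).
#'
#' @param matrices list of SummarizedExperiments with an \code{"exprs"} assay.
#' @return merged SummarizedExperiment.
#' @export
mergeCohorts <- function(matrices) {
  stopIfNot(is.list(matrices) && length(matrices) >= 1L,
            "need a non-empty list of matrices")
  mats <- lapply(matrices, function(x) {
    if (is.matrix(x)) x else SummarizedExperiment::assay(x, "exprs")
  })
  allSamples <- unlist(lapply(mats, colnames))
  dup <- unique(allSamples[duplicated(allSamples)])
  stopIfNot(length(dup) == 0L, "sample id collision(s) across cohorts: %s",
            paste(dup, collapse = ", "))
  genes <- Reduce(union, lapply(mats, rownames))
  out <- matrix(NA_real_, nrow = length(genes), ncol = length(allSamples),
                dimnames = list(genes, allSamples))
  for (m in mats) out[rownames(m), colnames(m)] <- m
  cds <- lapply(matrices, function(x) {
    if (is.matrix(x)) NULL else as.data.frame(SummarizedExperiment::colData(x))
  })
  se <- SummarizedExperiment::SummarizedExperiment(assays = list(exprs = out))
  if (!any(vapply(cds, is.null, logical(1L))) &&
      all(vapply(cds, ncol, 0L) > 0L)) {
    cols <- Reduce(union, lapply(cds, colnames))
    cds <- lapply(cds, function(d) {
      for (col in setdiff(cols, colnames(d))) d[[col]] <- "unknown"
      d[, cols, drop = FALSE]
    })
    cd <- do.call(rbind, cds)
    rownames(cd) <- allSamples
    SummarizedExperiment::colData(se) <- S4Vectors::DataFrame(cd)
  }
  se
}
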