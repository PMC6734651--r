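## Baseline-table statistics: Pearson chi-square (no continuity correction)
## or Fisher's exact test for nominal variables, pooled-variance Student t
## for continuous summaries, tie-corrected Mann-Whitney U (normal
## approximation, no continuity correction) for ordinal variables. Missing
## values are excluded from every test.

as2x2 <- function(tab) {
  m <- if (is.matrix(tab)) tab else matrix(tab, 2L, 2L, byrow = TRUE)
  stopIfNot(all(dim(m) == 2L), "need a 2x2 table")
  stopIfNot(all(m >= 0) && all(m == round(m)), "counts must be non-negative integers")
  m
}

#' Pearson chi-square test for a 2x2 table
#'
#' Closed form \eqn{\chi^2 = n(ad-bc)^2/(r_1 r_2 c_1 c_2)} with no
#' continuity correction; two-sided p from the chi-square(1) distribution.
#'
#' @param tab 2x2 matrix of counts, or a length-4 vector (a, b, c, d)
#'   filled row-wise.
#' @return list with \code{statistic} and \code{p.value}.
#' @examples
#' pearsonChi2x2(c(102, 312, 103, 372))$p.value  # ~0.297
#' @export
pearsonChi2x2 <- function(tab) {
  m <- as2x2(tab)
  r <- rowSums(m); cl <- colSums(m); n <- sum(m)
  stopIfNot(all(r > 0) && all(cl > 0),
            "zero margin: use fisherExact2x2() instead")
  chi2 <- n * (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])^2 /
    (r[1] * r[2] * cl[1] * cl[2])
  list(statistic = unname(chi2),
       p.value = stats::pchisq(unname(chi2), df = 1L, lower.tail = FALSE))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p by full hypergeometric enumeration: over all tables with the
#' observed margins, sums the probabilities of tables no more probable than
#' the observed one (with a 1e-7 relative tolerance for floating-point
#' ties).
#'
#' @param tab 2x2 matrix of counts or length-4 row-wise vector.
#' @return two-sided p-value.
#' @export
fisherExact2x2 <- function(tab) {
  m <- as2x2(tab)
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  if (n == 0L) return(1)
  kRange <- max(0L, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(kRange, c1, n - c1, r1)
  pObs <- stats::dhyper(m[1, 1], c1, n - c1, r1)
  min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

#' Pooled-variance two-sample t test from group summaries
#'
#' Student's t with pooled variance, \eqn{df = n_a + n_b - 2}, two-sided p,
#' computed from per-group mean, SD and n (as printed in a baseline table).
#'
#' @param meanA,sdA,nA,meanB,sdB,nB group summaries; \code{nA, nB >= 2},
#'   SDs non-negative.
#' @return list with \code{statistic}, \code{df}, \code{p.value}.
#' @examples
#' studentTSummary(68.37, 12.91, 205, 67.08, 13.11, 684)$p.value  # ~0.215
#' @export
studentTSummary <- function(meanA, sdA, nA, meanB, sdB, nB) {
  stopIfNot(nA >= 2 && nB >= 2, "both groups need n >= 2")
  stopIfNot(sdA >= 0 && sdB >= 0, "SDs must be non-negative")
  df <- nA + nB - 2
  sp2 <- ((nA - 1) * sdA^2 + (nB - 1) * sdB^2) / df
  if (sp2 == 0) {
    stopIfNot(meanA == meanB,
              "zero pooled variance with unequal means: t undefined")
    return(list(statistic = 0, df = df, p.value = 1))
  }
  t <- (meanA - meanB) / sqrt(sp2 * (1 / nA + 1 / nB))
  list(statistic = t, df = df,
       p.value = 2 * stats::pt(-abs(t), df))
}

#' Mann-Whitney U test on ordinal category counts
#'
#' Midranks are assigned per category; U is computed for group A and tested
#' with the tie-corrected normal approximation
#' \eqn{Var = n_a n_b/12 [(n+1) - \sum(t^3-t)/(n(n-1))]}, no continuity
#' correction, two-sided p.
#'
#' @param countsA,countsB integer counts per ordered category (same length
#'   >= 2, same category order; both groups non-empty).
#' @return list with \code{U}, \code{z}, \code{p.value}.
#' @examples
#' mannWhitneyOrdinal(c(4, 116, 85), c(78, 362, 244))$p.value  # ~0.006
#' @export
mannWhitneyOrdinal <- function(countsA, countsB) {
  stopIfNot(length(countsA) == length(countsB) && length(countsA) >= 2L,
            "need counts over >= 2 shared ordered categories")
  stopIfNot(all(countsA >= 0) && all(countsB >= 0), "counts must be >= 0")
  nA <- sum(countsA); nB <- sum(countsB)
  stopIfNot(nA > 0 && nB > 0, "both groups must be non-empty")
  tot <- countsA + countsB
  n <- nA + nB
  midrank <- cumsum(tot) - (tot - 1) / 2
  rA <- sum(countsA * midrank)
  U <- rA - nA * (nA + 1) / 2
  mu <- nA * nB / 2
  v <- nA * nB / 12 * ((n + 1) - sum(tot^3 - tot) / (n * (n - 1)))
  if (v <= 0) return(list(U = U, z = 0, p.value = 1))
  z <- (U - mu) / sqrt(v)
  list(U = U, z = z, p.value = 2 * stats::pnorm(-abs(z)))
}

## Dispatch a 2-level nominal comparison: chi-square unless any expected
## cell count is below 5, then Fisher.
nominalTest <- function(m) {
  r <- rowSums(m); cl <- colSums(m); n <- sum(m)
  if (any(r == 0) || any(cl == 0)) {
    return(list(p.value = NA_real_, test = "skipped (single category)"))
  }
  expected <- outer(r, cl) / n
  if (any(expected < 5)) {
    list(p.value = fisherExact2x2(m), test = "Fisher exact")
  } else {
    list(p.value = pearsonChi2x2(m)$p.value, test = "chi-square")
  }
}

fmtCount <- function(k, n) sprintf("%d (%.1f)", k, 100 * k / max(n, 1L))

#' Baseline comparison table for a dichotomized cohort
#'
#' Compares the two marker groups variable by variable, dispatching per
#' type: nominal (sex, location, chemo) to chi-square, falling back to
#' Fisher's exact test when any expected cell count is below 5; continuous
#' (age) to the pooled t test; ordinal (stage, grade) to the tie-corrected
#' Mann-Whitney U test. Rows with a missing/unknown level are excluded from
#' the test but displayed. Serum CEA and CA19-9 are displayed as median
#' (range) without a test. Variables with a single observed category are
#' skipped with a note.
#'
#' @param clinical clinical data.frame (see \code{\link{readClinicalTable}}).
#' @param grouping two-level factor (or character) per patient, aligned
#'   with \code{clinical} rows or named by \code{patient_id}; the first
#'   level is reported in the first column.
#' @return data.frame with columns \code{variable}, \code{category},
#'   display strings per group, \code{p.value} (full precision, on the
#'   variable's first row), \code{p.display} (3 decimals) and \code{test}.
#' @export
baselineTable <- function(clinical, grouping) {
  if (!is.null(names(grouping))) {
    grouping <- grouping[clinical$patient_id]
  }
  stopIfNot(length(grouping) == nrow(clinical),
            "grouping must cover every patient")
  stopIfNot(!anyNA(grouping), "grouping must be defined for every patient")
  g <- factor(grouping)
  stopIfNot(nlevels(g) == 2L, "grouping must have exactly 2 levels")
  gl <- levels(g)
  rows <- list()
  addRow <- function(variable, category, a, b, p = NA_real_, test = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, category = category, a = a, b = b,
      p.value = p, test = test, stringsAsFactors = FALSE)
  }
  nominalVar <- function(variable, values, levelsShown, missingLevels) {
    v <- as.character(values)
    used <- v %in% levelsShown
    tab <- vapply(levelsShown, function(lv) {
      c(sum(v == lv & g == gl[1L]), sum(v == lv & g == gl[2L]))
    }, numeric(2L))
    m <- t(tab)   # levels x groups -> want 2 groups cols
    res <- if (sum(rowSums(m) > 0) < 2L) {
      list(p.value = NA_real_, test = "skipped (single category)")
    } else {
      nominalTest(t(m))  # groups x levels
    }
    nAg <- sum(used & g == gl[1L]); nBg <- sum(used & g == gl[2L])
    for (i in seq_along(levelsShown)) {
      addRow(variable, levelsShown[i],
             fmtCount(m[i, 1L], sum(g == gl[1L])),
             fmtCount(m[i, 2L], sum(g == gl[2L])),
             if (i == 1L) res$p.value else NA_real_,
             if (i == 1L) res$test else "")
    }
    for (ml in missingLevels) {
      nmA <- sum(v == ml & g == gl[1L]); nmB <- sum(v == ml & g == gl[2L])
      if (nmA + nmB > 0) {
        addRow(variable, paste0(toupper(substring(ml, 1, 1)),
                                substring(ml, 2)),
               fmtCount(nmA, sum(g == gl[1L])),
               fmtCount(nmB, sum(g == gl[2L])))
      }
    }
  }
  ordinalVar <- function(variable, values, levelsOrdered) {
    v <- as.character(values)
    cA <- vapply(levelsOrdered, function(lv) sum(v == lv & g == gl[1L]), 0)
    cB <- vapply(levelsOrdered, function(lv) sum(v == lv & g == gl[2L]), 0)
    res <- if (sum(cA) == 0 || sum(cB) == 0 || sum(cA + cB > 0) < 2L) {
      list(p.value = NA_real_, test = "skipped (single category)")
    } else {
      r <- mannWhitneyOrdinal(cA, cB)
      list(p.value = r$p.value, test = "Mann-Whitney U")
    }
    for (i in seq_along(levelsOrdered)) {
      addRow(variable, levelsOrdered[i],
             fmtCount(cA[i], sum(cA)), fmtCount(cB[i], sum(cB)),
             if (i == 1L) res$p.value else NA_real_,
             if (i == 1L) res$test else "")
    }
  }
  ## age: mean (SD), pooled t
  a <- clinical$age[g == gl[1L]]; b <- clinical$age[g == gl[2L]]
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) >= 2L && length(b) >= 2L) {
    tt <- studentTSummary(mean(a), stats::sd(a), length(a),
                          mean(b), stats::sd(b), length(b))
    addRow("age", "mean (SD)",
           sprintf("%.2f (%.2f)", mean(a), stats::sd(a)),
           sprintf("%.2f (%.2f)", mean(b), stats::sd(b)),
           tt$p.value, "Student t")
  }
  nominalVar("sex", clinical$sex, c("F", "M"), character())
  if ("location" %in% colnames(clinical)) {
    nominalVar("location", clinical$location, c("colon", "rectum"), "unknown")
  }
  if ("grade" %in% colnames(clinical)) {
    ordinalVar("grade", clinical$grade, c("well", "moderate", "poor"))
  }
  ordinalVar("stage", clinical$stage, c("I", "II", "III"))
  if ("chemo" %in% colnames(clinical)) {
    nominalVar("chemo", clinical$chemo, c("yes", "no"), "missing")
  }
  for (serum in intersect(c("cea", "ca199"), colnames(clinical))) {
    a <- clinical[[serum]][g == gl[1L]]; b <- clinical[[serum]][g == gl[2L]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) && length(b)) {
      addRow(serum, "median (range)",
             sprintf("%.2f (%.2f-%.2f)", stats::median(a), min(a), max(a)),
             sprintf("%.2f (%.2f-%.2f)", stats::median(b), min(b), max(b)),
             NA_real_, "display only")
    }
  }
  out <- do.call(rbind, rows)
  colnames(out)[3:4] <- gl
  out$p.display <- ifelse(is.na(out$p.value), "",
                          sprintf("%.3f", out$p.value))
  out
}
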