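## Marker-based patient subgrouping and the survival battery: Kaplan-Meier
## curves with 5-year rates, log-rank tests, multivariate Cox models
## (Efron ties by default), stage-restricted reruns and the 2x2 factorial
## marker-by-chemotherapy interaction (multiplicative product term and
## additive RERI with a delta-method CI). The estimators themselves come
## from the survival package; this layer owns the encodings and reporting.

#' Assign two- and three-group marker labels from Boolean calls
#'
#' Patient-level calls should be produced with margin 0 so every patient is
#' LOW or HIGH. The two-group label follows the marker gene alone
#' (\code{low}/\code{high}); the three-group label crosses it with the
#' partner (VIM-like) gene: \code{low_high}, \code{high_high},
#' \code{high_low}, with the sparse marker-low/partner-low cell labelled
#' \code{other}. Patients with an INTERMEDIATE or MISSING call in a used
#' gene are excluded with a logged count.
#'
#' @param callsMarker marker-gene calls per patient (factor/character in
#'   LOW/INTERMEDIATE/HIGH/MISSING, or integer codes), named by patient.
#' @param callsPartner optional partner-gene calls over the same patients;
#'   required for the three-group label.
#' @return data.frame with \code{patient_id}, \code{twoGroup} and (when the
#'   partner is supplied) \code{threeGroup}.
#' @export
assignMarkerGroups <- function(callsMarker, callsPartner = NULL) {
  cm <- asCallCodes(callsMarker)
  ids <- if (!is.null(names(cm))) names(cm) else as.character(seq_along(cm))
  okM <- !is.na(cm) & cm != 1L
  if (is.null(callsPartner)) {
    if (any(!okM)) {
      bsLog("assignMarkerGroups: %d patient(s) excluded (no LOW/HIGH marker call)",
            sum(!okM))
    }
    return(data.frame(
      patient_id = ids[okM],
      twoGroup = factor(ifelse(cm[okM] == 0L, "low", "high"),
                        levels = c("low", "high")),
      stringsAsFactors = FALSE, row.names = NULL))
  }
  cp <- asCallCodes(callsPartner)
  stopIfNot(length(cp) == length(cm),
            "marker and partner call vectors differ in length")
  if (!is.null(names(cp))) cp <- cp[ids]
  ok <- okM & !is.na(cp) & cp != 1L
  if (any(!ok)) {
    bsLog("assignMarkerGroups: %d patient(s) excluded (no LOW/HIGH call in both genes)",
          sum(!ok))
  }
  mLow <- cm[ok] == 0L
  pLow <- cp[ok] == 0L
  three <- ifelse(mLow & !pLow, "low_high",
                  ifelse(!mLow & !pLow, "high_high",
                         ifelse(!mLow & pLow, "high_low", "other")))
  nOther <- sum(three == "other")
  if (nOther > 0) {
    bsLog("assignMarkerGroups: %d patient(s) in the sparse marker-low/partner-low cell (OTHER)",
          nOther)
  }
  data.frame(
    patient_id = ids[ok],
    twoGroup = factor(ifelse(mLow, "low", "high"), levels = c("low", "high")),
    threeGroup = factor(three,
                        levels = c("low_high", "high_high", "high_low",
                                   "other")),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimator via \code{\link[survival]{survfit}}.
#'
#' @param times positive follow-up times (months).
#' @param events 0/1 event indicators.
#' @param groups optional grouping factor for stratified curves.
#' @return a \code{survfit} object.
#' @export
kmEstimate <- function(times, events, groups = NULL) {
  stopIfNot(length(times) > 0L, "empty input")
  stopIfNot(all(times > 0), "times must be strictly positive")
  stopIfNot(all(events %in% c(0, 1)), "events must be 0/1")
  if (is.null(groups)) {
    survival::survfit(survival::Surv(times, events) ~ 1)
  } else {
    df <- data.frame(times = times, events = events, groups = groups)
    survival::survfit(survival::Surv(times, events) ~ groups, data = df)
  }
}

#' Survival probability at a time point
#'
#' Reads the right-continuous step function: S at the largest event time
#' \eqn{\le t}; the 5-year rate is \code{survivalAt(curve, 60)}.
#'
#' @param curve a \code{survfit} object.
#' @param tMonths time point in months.
#' @return survival probability; a named vector when the curve has strata.
#' @export
survivalAt <- function(curve, tMonths) {
  s <- summary(curve, times = tMonths, extend = TRUE)
  if (is.null(curve$strata)) {
    unname(s$surv)
  } else {
    stats::setNames(s$surv, sub("^groups=", "", as.character(s$strata)))
  }
}

#' Log-rank test
#'
#' Standard log-rank chi-square with G - 1 degrees of freedom via
#' \code{\link[survival]{survdiff}} (rho = 0), two-sided p.
#'
#' @inheritParams kmEstimate
#' @param groups grouping factor with >= 2 non-empty groups.
#' @return list with \code{statistic}, \code{df}, \code{p.value}.
#' @export
logrankTest <- function(times, events, groups) {
  g <- factor(groups)
  g <- droplevels(g)
  stopIfNot(nlevels(g) >= 2L, "log-rank needs >= 2 non-empty groups")
  df <- data.frame(times = times, events = events, g = g)
  sd <- survival::survdiff(survival::Surv(times, events) ~ g, data = df)
  ndf <- length(sd$n) - 1L
  list(statistic = unname(sd$chisq), df = ndf,
       p.value = stats::pchisq(unname(sd$chisq), ndf, lower.tail = FALSE))
}

## Covariate encodings used throughout: marker group low vs high (reference
## high), age dichotomized >= 60 vs < 60, sex male vs female, stage numeric
## "per increase in stage", chemo yes vs no with missing excluded
## (complete case), location colon vs rectum, grade poorly vs others.
encodeCovariates <- function(clinical, covariates) {
  df <- data.frame(row.names = seq_len(nrow(clinical)))
  for (cv in covariates) {
    df[[cv]] <- switch(
      cv,
      group = factor(as.character(clinical$group),
                     levels = c("high", "low")),
      age60 = factor(ifelse(clinical$age >= 60, ">=60", "<60"),
                     levels = c("<60", ">=60")),
      sex = factor(clinical$sex, levels = c("F", "M")),
      stage = as.numeric(clinical$stage),
      chemo = factor(ifelse(clinical$chemo %in% c("yes", "no"),
                            clinical$chemo, NA),
                     levels = c("no", "yes")),
      location = factor(ifelse(clinical$location %in% c("colon", "rectum"),
                               clinical$location, NA),
                        levels = c("rectum", "colon")),
      grade = factor(ifelse(clinical$grade == "unknown", NA,
                            ifelse(clinical$grade == "poor", "poorly",
                                   "others")),
                     levels = c("others", "poorly")),
      stop(sprintf("unknown covariate '%s'", cv), call. = FALSE)
    )
  }
  df
}

endpointColumns <- function(clinical, endpoint) {
  endpoint <- match.arg(endpoint, c("DFS", "DSS"))
  cols <- if (endpoint == "DFS") c("dfs_months", "dfs_event")
          else c("dss_months", "dss_event")
  missingCols <- setdiff(cols, colnames(clinical))
  stopIfNot(length(missingCols) == 0L, "clinical table lacks %s column(s): %s",
            endpoint, paste(missingCols, collapse = ", "))
  cols
}

#' Multivariate Cox proportional-hazards fit
#'
#' Partial-likelihood fit via \code{\link[survival]{coxph}} with Efron tie
#' handling by default. Covariates are encoded by convention: \code{group}
#' low vs. high (reference high), \code{age60} >= 60 vs. < 60, \code{sex}
#' male vs. female, \code{stage} numeric per increase in stage,
#' \code{chemo} yes vs. no with missing excluded, \code{location} colon
#' vs. rectum, \code{grade} poorly vs. others. Rows with a missing
#' covariate are dropped complete-case with a logged count.
#'
#' @param clinical clinical data.frame; must carry a \code{group} column
#'   when \code{"group"} is among the covariates.
#' @param endpoint \code{"DFS"} or \code{"DSS"}.
#' @param covariates character vector among group, age60, sex, stage,
#'   chemo, location, grade.
#' @param ties \code{"efron"} (default) or \code{"breslow"}.
#' @return list with \code{table} (term, HR, lo, hi, p), \code{loglik},
#'   \code{n}, \code{nEvent}, \code{separation} flag and the underlying
#'   \code{fit}.
#' @export
coxFit <- function(clinical, endpoint = "DFS", covariates = "group",
                   ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  cols <- endpointColumns(clinical, endpoint)
  enc <- encodeCovariates(clinical, covariates)
  dat <- cbind(data.frame(.time = clinical[[cols[1L]]],
                          .event = clinical[[cols[2L]]]), enc)
  complete <- stats::complete.cases(dat)
  if (any(!complete)) {
    bsLog("coxFit: %d row(s) excluded complete-case (missing covariate or endpoint)",
          sum(!complete))
  }
  dat <- dat[complete, , drop = FALSE]
  stopIfNot(sum(dat$.event) >= 1, "no events in the analysis set")
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = ties)
  stopIfNot(is.finite(fit$loglik[2L]), "Cox fit did not converge")
  sm <- summary(fit)
  co <- sm$coefficients
  ci <- sm$conf.int
  separation <- any(abs(co[, "coef"]) > 15)
  if (separation) bsLog("coxFit: possible separation (|coef| > 15)")
  tab <- data.frame(
    term = rownames(co),
    HR = unname(co[, "exp(coef)"]),
    lo = unname(ci[, "lower .95"]),
    hi = unname(ci[, "upper .95"]),
    p = unname(co[, "Pr(>|z|)"]),
    stringsAsFactors = FALSE, row.names = NULL)
  list(table = tab, loglik = unname(fit$loglik[2L]), n = sm$n,
       nEvent = sm$nevent, separation = separation, fit = fit)
}

#' Marker-by-chemotherapy interaction in a 2x2 factorial Cox design
#'
#' Tests whether marker status (low vs. high) and adjuvant chemotherapy
#' (yes vs. no) act multiplicatively or additively on the hazard. The
#' multiplicative component is the Wald test of the product term in a Cox
#' model with both main effects; the additive component is the relative
#' excess risk due to interaction, \eqn{RERI = HR_{11} - HR_{10} - HR_{01}
#' + 1}, from the joint-indicator parameterization with a delta-method 95
#' percent CI (RERI = 0 under hazard additivity). Patients with missing
#' chemotherapy are excluded; "exposed" cells are marker-low and
#' chemo-yes, with marker-high/chemo-no as the reference.
#'
#' @param clinical clinical data.frame with a \code{group} (low/high) and
#'   \code{chemo} (yes/no/missing) column.
#' @param endpoint \code{"DFS"} or \code{"DSS"}.
#' @param ties tie handling passed to \code{coxph}.
#' @return list with \code{multiplicative} (coef, se, p), \code{additive}
#'   (reri, se, lo, hi) and \code{HR} (hr10, hr01, hr11 vs. the reference
#'   cell).
#' @export
chemoInteraction <- function(clinical, endpoint = "DFS",
                             ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  cols <- endpointColumns(clinical, endpoint)
  use <- clinical$chemo %in% c("yes", "no") &
    as.character(clinical$group) %in% c("low", "high")
  nExcluded <- sum(!use)
  if (nExcluded > 0) {
    bsLog("chemoInteraction: %d patient(s) excluded (missing chemo or group)",
          nExcluded)
  }
  d <- clinical[use, , drop = FALSE]
  marker <- as.integer(as.character(d$group) == "low")
  chemo <- as.integer(d$chemo == "yes")
  cells <- table(factor(marker, 0:1), factor(chemo, 0:1))
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    stop(sprintf("empty factorial cell(s): %s",
                 paste(sprintf("marker=%s/chemo=%s",
                               c("high", "low")[empty[, 1L]],
                               c("no", "yes")[empty[, 2L]]),
                       collapse = ", ")), call. = FALSE)
  }
  dat <- data.frame(.time = d[[cols[1L]]], .event = d[[cols[2L]]],
                    marker = marker, chemo = chemo)
  ## multiplicative: product term
  fitM <- survival::coxph(
    survival::Surv(.time, .event) ~ marker * chemo, data = dat, ties = ties)
  coM <- summary(fitM)$coefficients
  mult <- list(coef = unname(coM["marker:chemo", "coef"]),
               se = unname(coM["marker:chemo", "se(coef)"]),
               p = unname(coM["marker:chemo", "Pr(>|z|)"]))
  ## additive: joint-indicator parameterization
  cell <- factor(paste0(marker, chemo), levels = c("00", "10", "01", "11"))
  dat$cell <- cell
  fitA <- survival::coxph(
    survival::Surv(.time, .event) ~ cell, data = dat, ties = ties)
  b <- stats::coef(fitA)
  V <- stats::vcov(fitA)
  hr <- exp(b)
  reri <- hr[["cell11"]] - hr[["cell10"]] - hr[["cell01"]] + 1
  grad <- c(cell10 = -hr[["cell10"]], cell01 = -hr[["cell01"]],
            cell11 = hr[["cell11"]])
  grad <- grad[names(b)]
  se <- sqrt(drop(t(grad) %*% V %*% grad))
  list(
    multiplicative = mult,
    additive = list(reri = reri, se = se,
                    lo = reri - stats::qnorm(0.975) * se,
                    hi = reri + stats::qnorm(0.975) * se),
    HR = list(hr10 = hr[["cell10"]], hr01 = hr[["cell01"]],
              hr11 = hr[["cell11"]]))
}

#' Stage-restricted survival analysis
#'
#' Restricts the cohort to the selected stages and reruns the Kaplan-Meier
#' estimate, the log-rank test across marker groups and the per-group
#' 5-year rates.
#'
#' @param clinical clinical data.frame with a \code{group} column.
#' @param endpoint \code{"DFS"} or \code{"DSS"}.
#' @param stages non-empty subset of \code{c("I", "II", "III")}.
#' @return list with \code{stages}, \code{n}, \code{km} (survfit by
#'   group), \code{logrank} and \code{fiveYear} (named per-group rates at
#'   60 months).
#' @export
stageSubsetAnalysis <- function(clinical, endpoint = "DFS",
                                stages = c("I", "II", "III")) {
  stopIfNot(length(stages) > 0L, "empty stage subset")
  stopIfNot(all(stages %in% c("I", "II", "III")),
            "stages must be within I/II/III")
  cols <- endpointColumns(clinical, endpoint)
  d <- clinical[as.character(clinical$stage) %in% stages, , drop = FALSE]
  stopIfNot(nrow(d) > 0L, "no patients in stage subset {%s}",
            paste(stages, collapse = ", "))
  km <- kmEstimate(d[[cols[1L]]], d[[cols[2L]]], groups = d$group)
  lr <- logrankTest(d[[cols[1L]]], d[[cols[2L]]], d$group)
  list(stages = stages, n = nrow(d), km = km, logrank = lr,
       fiveYear = survivalAt(km, 60))
}
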