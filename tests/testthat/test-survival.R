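test_that("marker groups follow the two-gene definition", {
  marker <- c(p1 = "LOW", p2 = "HIGH", p3 = "HIGH", p4 = "LOW",
              p5 = "INTERMEDIATE", p6 = "MISSING")
  partner <- c(p1 = "HIGH", p2 = "HIGH", p3 = "LOW", p4 = "LOW",
               p5 = "HIGH", p6 = "HIGH")
  localVerbose()
  expect_message(g <- assignMarkerGroups(marker, partner), "2 patient")
  expect_equal(nrow(g), 4L)
  expect_identical(as.character(g$twoGroup), c("low", "high", "high", "low"))
  expect_identical(as.character(g$threeGroup),
                   c("low_high", "high_high", "high_low", "other"))
  g2 <- assignMarkerGroups(marker)
  expect_identical(colnames(g2), c("patient_id", "twoGroup"))
})

test_that("Kaplan-Meier estimates match hand product-limit calculations", {
  allCens <- kmEstimate(c(3, 8, 12), c(0, 0, 0))
  expect_true(all(allCens$surv == 1))
  expect_equal(survivalAt(allCens, 60), 1)

  ## times 5+, 10, 15+, 20: S(10) = 3/4 at risk -> 2/3... hand calc:
  ## at t=10, 3 at risk, 1 event -> S = 2/3; at t=20, 1 at risk, 1 event -> 0
  km <- kmEstimate(c(5, 10, 15, 20), c(0, 1, 0, 1))
  expect_equal(survivalAt(km, 10), 2 / 3)
  expect_equal(survivalAt(km, 20), 0)
  ## right-continuous and piecewise constant between event times
  expect_equal(survivalAt(km, 12), 2 / 3)
  expect_equal(survivalAt(km, 19.99), 2 / 3)
  expect_equal(survivalAt(km, 9.99), 1)

  ## no censoring: empirical survival fraction
  tt <- c(2, 4, 6, 8, 10)
  km2 <- kmEstimate(tt, rep(1, 5))
  for (t0 in c(3, 5, 9)) {
    expect_equal(survivalAt(km2, t0), mean(tt > t0))
  }
  expect_error(kmEstimate(numeric(), numeric()), "empty")
})

test_that("log-rank is null on identical groups and powered under HR = 3", {
  tt <- c(3, 5, 8, 12, 20, 24)
  ev <- c(1, 0, 1, 1, 0, 1)
  lr <- logrankTest(c(tt, tt), c(ev, ev), rep(c("a", "b"), each = 6))
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p.value, 1, tolerance = 1e-12)

  set.seed(61)
  for (rep in 1:20) {
    t1 <- rexp(200, 0.01); t2 <- rexp(200, 0.03)
    cens <- runif(400, 0, 110)   # ~30% censoring
    tAll <- pmin(c(t1, t2), cens)
    eAll <- as.integer(c(t1, t2) <= cens)
    lr <- logrankTest(tAll, eAll, rep(c("a", "b"), each = 200))
    expect_lt(lr$p.value, 0.001)
  }
  expect_error(logrankTest(tt, ev, factor(rep("a", 6), levels = c("a", "b"))),
               ">= 2")
})

test_that("Cox fit reports unit HR for a non-informative covariate", {
  cfg <- smallConfig()
  clin <- generateClinical(cfg, rep("high", 200), seed = 62,
                           beta = 0)
  ## duplicate the cohort under both group labels: identical survival
  clin2 <- rbind(clin, clin)
  clin2$group <- factor(rep(c("low", "high"), each = 200),
                        levels = c("low", "high"))
  clin2$patient_id <- sprintf("p%03d", seq_len(400))
  fit <- coxFit(clin2, "DFS", "group")
  row <- fit$table[fit$table$term == "grouplow", ]
  expect_equal(row$HR, 1, tolerance = 1e-6)
  expect_true(row$lo <= 1 && 1 <= row$hi)
  ## CI endpoints are the exponentiated Wald limits of the coefficient
  co <- summary(fit$fit)$coefficients
  expect_equal(row$lo, exp(co[1, "coef"] - qnorm(0.975) * co[1, "se(coef)"]),
               tolerance = 1e-8)
  expect_equal(row$hi, exp(co[1, "coef"] + qnorm(0.975) * co[1, "se(coef)"]),
               tolerance = 1e-8)
})

test_that("Cox coefficient estimates are nearly unbiased at n = 2000", {
  cfg <- studyConfig(nDiscovery = 2000L)
  for (beta in c(0, log(1.37), log(4.05))) {
    est <- vapply(1:50, function(i) {
      set.seed(6300 + i)
      grp <- ifelse(runif(2000) < 0.25, "low", "high")
      clin <- generateClinical(cfg, grp, seed = 6300 + i, beta = beta)
      fit <- coxFit(clin, "DFS", c("group", "stage", "age60"))
      log(fit$table$HR[fit$table$term == "grouplow"])
    }, numeric(1L))
    expect_lt(abs(mean(est) - beta), 0.05)
  }
})

test_that("the factorial interaction separates multiplicative and additive scales", {
  ## multiplicative hazards: product term null, RERI = (HR10-1)(HR01-1)
  genFactorial <- function(n, seed, b10 = log(2), b01 = log(1.5),
                           b11 = log(2) + log(1.5)) {
    set.seed(seed)
    marker <- rbinom(n, 1, 0.4)
    chemo <- rbinom(n, 1, 0.5)
    lp <- b10 * marker * (1 - chemo) + b01 * chemo * (1 - marker) +
      b11 * marker * chemo
    tt <- rexp(n, 0.01 * exp(lp))
    cens <- runif(n, 0, 150)
    data.frame(
      patient_id = sprintf("p%04d", seq_len(n)),
      dfs_months = pmin(tt, cens), dfs_event = as.integer(tt <= cens),
      group = factor(ifelse(marker == 1, "low", "high"),
                     levels = c("low", "high")),
      chemo = ifelse(chemo == 1, "yes", "no"))
  }
  coefs <- vapply(1:10, function(i) {
    chemoInteraction(genFactorial(800, 6400 + i))$multiplicative$coef
  }, numeric(1L))
  expect_lt(abs(mean(coefs)), 0.1)
  res <- chemoInteraction(genFactorial(4000, 6499))
  expect_equal(res$additive$reri, (2 - 1) * (1.5 - 1), tolerance = 0.35)

  ## no-effect data: both interaction measures null
  null <- chemoInteraction(genFactorial(2000, 6500, 0, 0, 0))
  expect_lt(abs(null$multiplicative$coef), 0.3)
  expect_true(null$additive$lo <= 0 && 0 <= null$additive$hi)

  ## relabeling marker and chemo leaves the multiplicative p unchanged
  d <- genFactorial(600, 6501)
  swapped <- d
  swapped$group <- factor(ifelse(d$chemo == "yes", "low", "high"),
                          levels = c("low", "high"))
  swapped$chemo <- ifelse(d$group == "low", "yes", "no")
  expect_equal(chemoInteraction(swapped)$multiplicative$p,
               chemoInteraction(d)$multiplicative$p, tolerance = 1e-8)

  ## an empty factorial cell is a hard error naming the cell
  dEmpty <- d[!(d$group == "low" & d$chemo == "yes"), ]
  expect_error(chemoInteraction(dEmpty), "marker=low/chemo=yes")
})

test_that("additive-hazard data give RERI intervals covering zero", {
  ## additive hazards: h = h0 (1 + a*marker + b*chemo); RERI truth 0
  covered <- vapply(1:20, function(i) {
    set.seed(6600 + i)
    n <- 600
    marker <- rbinom(n, 1, 0.4)
    chemo <- rbinom(n, 1, 0.5)
    h <- 0.01 * (1 + 1.0 * marker + 0.5 * chemo)
    tt <- rexp(n, h)
    cens <- runif(n, 0, 120)
    d <- data.frame(patient_id = seq_len(n),
                    dfs_months = pmin(tt, cens),
                    dfs_event = as.integer(tt <= cens),
                    group = factor(ifelse(marker == 1, "low", "high"),
                                   levels = c("low", "high")),
                    chemo = ifelse(chemo == 1, "yes", "no"))
    res <- chemoInteraction(d)
    res$additive$lo <= 0 && 0 <= res$additive$hi
  }, logical(1L))
  expect_gte(mean(covered), 0.8)
})

test_that("stage restriction reruns the same analysis on the subset", {
  cfg <- smallConfig()
  set.seed(67)
  clin <- generateClinical(cfg, ifelse(runif(400) < 0.3, "low", "high"),
                           seed = 67, beta = log(4.05))
  full <- stageSubsetAnalysis(clin, "DFS", c("I", "II", "III"))
  direct <- logrankTest(clin$dfs_months, clin$dfs_event, clin$group)
  expect_equal(full$logrank$p.value, direct$p.value)
  expect_equal(full$n, nrow(clin))

  sub <- stageSubsetAnalysis(clin, "DFS", "II")
  expect_equal(sub$n, sum(clin$stage == "II"))
  ## stage-uniform planted effect keeps its direction in the subset
  expect_lt(sub$fiveYear[["low"]], sub$fiveYear[["high"]])
  expect_error(stageSubsetAnalysis(clin, "DFS", character()), "empty")
})
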