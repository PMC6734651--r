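test_that("generation is a pure function of config and seed", {
  cfg <- smallConfig()
  s1 <- generateStudy(cfg, 71)
  s2 <- generateStudy(cfg, 71)
  expect_identical(SummarizedExperiment::assay(s1$se, "exprs"),
                   SummarizedExperiment::assay(s2$se, "exprs"))
  expect_identical(s1$clinicalDiscovery, s2$clinicalDiscovery)
  expect_identical(s1$clinicalValidation, s2$clinicalValidation)
  expect_identical(s1$truth$markerLow, s2$truth$markerLow)
  s3 <- generateStudy(cfg, 72)
  expect_false(identical(SummarizedExperiment::assay(s1$se, "exprs"),
                         SummarizedExperiment::assay(s3$se, "exprs")))
  ## written TSVs are byte-identical across runs of the same seed
  d1 <- tempfile(); d2 <- tempfile()
  generateStudy(cfg, 71, outDir = d1)
  generateStudy(cfg, 71, outDir = d2)
  for (f in c("matrix.tsv", "annotations.tsv", "clinical_discovery.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("adding genes does not perturb existing gene streams", {
  cfgSmall <- smallConfig(nGenes = 60L)
  cfgBig <- smallConfig(nGenes = 80L)
  a <- generateExpression(cfgSmall, 73)
  b <- generateExpression(cfgBig, 73)
  shared <- rownames(a$se)
  expect_identical(SummarizedExperiment::assay(a$se, "exprs")[shared, ],
                   SummarizedExperiment::assay(b$se, "exprs")[shared, ])
})

test_that("the marker-low fraction converges to its target", {
  cfg <- studyConfig(nCRC = 2480L, nPolyp = 0L, nIBD = 0L, nNormal = 0L,
                     nGenes = 5L, nBimodal = 1L, nDE = 1L)
  study <- generateExpression(cfg, 74)
  frac <- mean(study$truth$markerLow, na.rm = TRUE)
  expect_lt(abs(frac - 0.226), 0.03)
})

test_that("the sparse-quadrant leak converges to eps", {
  cfg <- studyConfig(nCRC = 5000L, nPolyp = 0L, nIBD = 0L, nNormal = 0L,
                     nGenes = 5L, nBimodal = 1L, nDE = 1L, eps = 0.02)
  study <- generateExpression(cfg, 75)
  mLow <- study$truth$markerLow
  tLow <- study$truth$targetLow
  leak <- mean(tLow[which(mLow)])
  se2 <- 2 * sqrt(0.02 * 0.98 / sum(mLow, na.rm = TRUE))
  expect_lt(abs(leak - 0.02), se2)
})

test_that("config invariants are enforced", {
  expect_error(studyConfig(piLow = 1.2), "piLow")
  expect_error(studyConfig(eps = 1), "eps")
  expect_error(studyConfig(nGenes = 10L, nBimodal = 20L), "planted")
  expect_error(studyConfig(censoringRate = 1), "censoringRate")
})

test_that("clinical generation hits the censoring target or errors", {
  cfg <- smallConfig(censoringRate = 0)
  set.seed(76)
  clinAll <- generateClinical(cfg, ifelse(runif(300) < 0.25, "low", "high"),
                              seed = 76)
  expect_true(all(clinAll$dfs_event == 1L))
  expect_true(all(clinAll$dfs_months > 0))

  cfg7 <- smallConfig(censoringRate = 0.7)
  clin <- generateClinical(cfg7, rep(c("low", "high"), 500), seed = 77)
  expect_lt(abs(mean(clin$dfs_event == 0L) - 0.7), 0.06)

  cfgBad <- smallConfig(censoringRate = 0.5, horizonMonths = 1)
  expect_error(generateClinical(cfgBad, rep("high", 50), seed = 78),
               "unreachable")
})

test_that("a null hazard yields confidence intervals covering 1", {
  cfg <- smallConfig(nDiscovery = 400L)
  covered <- vapply(1:20, function(i) {
    set.seed(7900 + i)
    grp <- ifelse(runif(400) < 0.3, "low", "high")
    clin <- generateClinical(cfg, grp, seed = 7900 + i, beta = 0)
    fit <- coxFit(clin, "DFS", c("group", "stage", "age60"))
    row <- fit$table[fit$table$term == "grouplow", ]
    row$lo <= 1 && 1 <= row$hi
  }, logical(1L))
  expect_gte(mean(covered), 0.8)
})

test_that("cohort sizes follow the configuration exactly", {
  cfg <- smallConfig(nDiscovery = 889L, nValidation = 691L)
  study <- generateStudy(cfg, 80)
  expect_equal(nrow(study$clinicalDiscovery), 889L)
  expect_equal(nrow(study$clinicalValidation), 691L)
  expect_equal(ncol(study$se), 200L + 10L + 40L + 40L)
})

test_that("a strong planted hazard separates the five-year survival rates", {
  cfg <- smallConfig(nValidation = 691L)
  study <- generateStudy(cfg, 81)
  clin <- study$clinicalValidation
  km <- kmEstimate(clin$dfs_months, clin$dfs_event, clin$group)
  fy <- survivalAt(km, 60)
  expect_lt(fy[["low"]], fy[["high"]] - 0.1)
})

test_that("the default study supports full pipeline recovery end to end", {
  cfg <- studyConfig(nCRC = 300L, nPolyp = 10L, nIBD = 60L, nNormal = 60L,
                     nGenes = 200L, nBimodal = 20L)
  study <- generateStudy(cfg, 82)
  cs <- thresholdAllGenes(study$se, margin = 0.5)
  ann <- study$annotations
  pop <- ann$sample_id[ann$tissue_class == "CRC"]
  res <- searchPartners(cs, cfg$targetGene, population = pop)
  expect_identical(res$gene[1L], cfg$markerGene)
  deN <- differentialExpression(study$se, pop,
                                ann$sample_id[ann$tissue_class == "normal"])
  deI <- differentialExpression(study$se, pop,
                                ann$sample_id[ann$tissue_class == "IBD"])
  sc <- screenCandidates(res[res$passes, ], deN, deI)
  expect_true(cfg$markerGene %in% sc$gene[sc$candidate])
  ## the planted marker's low group carries excess hazard in Cox
  fit <- coxFit(study$clinicalDiscovery, "DFS",
                c("group", "stage", "age60"))
  expect_gt(fit$table$HR[fit$table$term == "grouplow"], 1)
})
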