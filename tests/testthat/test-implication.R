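test_that("quadrant counts exclude intermediates and missings", {
  q <- quadrantCounts(c("L1" = "LOW", "L2" = "LOW", "H1" = "HIGH",
                        "H2" = "HIGH"),
                      c("L1" = "HIGH", "L2" = "HIGH", "H1" = "LOW",
                        "H2" = "HIGH"))
  expect_equal(q[c("nLL", "nLH", "nHL", "nHH")],
               list(nLL = 0L, nLH = 2L, nHL = 1L, nHH = 1L))
  expect_equal(q$n, 4L)

  q2 <- quadrantCounts(c("LOW", "LOW", "INTERMEDIATE", "HIGH"),
                       c("HIGH", "HIGH", "HIGH", "HIGH"))
  expect_equal(q2$n, 3L)
  expect_equal(q2$nExcluded, 1L)

  q3 <- quadrantCounts(rep("INTERMEDIATE", 4L), rep("INTERMEDIATE", 4L))
  expect_equal(q3$n, 0L)
  expect_error(quadrantCounts(c(a = "LOW"), c(b = "LOW")), "sample sets")
})

test_that("totals are conserved: n plus excluded pairs equals sample count", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(10:60, 1L)
    cx <- sample(c(0:2, NA), n, replace = TRUE)
    cy <- sample(c(0:2, NA), n, replace = TRUE)
    q <- quadrantCounts(cx, cy)
    expect_equal(q$n + q$nExcluded, n)
    expect_equal(q$nLL + q$nLH + q$nHL + q$nHH, q$n)
  }
})

test_that("the sparse-quadrant statistic matches direct arithmetic", {
  mk <- function(ll, lh, hl, hh) {
    structure(list(nLL = ll, nLH = lh, nHL = hl, nHH = hh,
                   n = ll + lh + hl + hh, nExcluded = 0L),
              class = "QuadrantCounts")
  }
  ## empty sparse quadrant: S = sqrt(e), err = 0
  s1 <- implicationStatistic(mk(0, 10, 10, 10))
  expect_equal(s1$expected, 10 * 10 / 30)
  expect_equal(s1$statistic, sqrt(10 * 10 / 30))
  expect_equal(s1$errorRate, 0)

  ## exact independence: S = 0, err = 0.5
  s2 <- implicationStatistic(mk(25, 25, 25, 25))
  expect_equal(s2$statistic, 0)
  expect_equal(s2$errorRate, 0.5)
  expect_false(s2$passes)

  ## direct arithmetic oracle: e = 50*40/150, S = (e-2)/sqrt(e),
  ## err = (2/50 + 2/40)/2
  s3 <- implicationStatistic(mk(2, 48, 38, 62), sMin = 3, errMax = 0.1)
  e <- 50 * 40 / 150
  expect_equal(s3$expected, e)
  expect_equal(s3$statistic, (e - 2) / sqrt(e))
  expect_equal(s3$statistic, 3.104, tolerance = 1e-3)
  expect_equal(s3$errorRate, 0.045)
  expect_true(s3$passes)

  ## zero margin for the tested quadrant -> not evaluable, no pass
  s4 <- implicationStatistic(mk(0, 0, 10, 10))
  expect_false(s4$evaluable)
  expect_false(s4$passes)
  expect_true(is.na(s4$statistic))
})

test_that("contrapositive pairs share statistic and error rate", {
  mk <- function(ll, lh, hl, hh) {
    structure(list(nLL = ll, nLH = lh, nHL = hl, nHH = hh,
                   n = ll + lh + hl + hh, nExcluded = 0L),
              class = "QuadrantCounts")
  }
  set.seed(32)
  for (rep in 1:10) {
    cnt <- sample(0:40, 4L, replace = TRUE)
    a <- implicationStatistic(mk(cnt[1], cnt[2], cnt[3], cnt[4]))
    ## swap the roles of X and Y: transpose the table
    b <- implicationStatistic(mk(cnt[1], cnt[3], cnt[2], cnt[4]))
    expect_equal(a$statistic, b$statistic)
    expect_equal(a$errorRate, b$errorRate)
  }
})

test_that("scaling all counts by k scales S by sqrt(k) exactly", {
  mk <- function(v) {
    structure(list(nLL = v[1], nLH = v[2], nHL = v[3], nHH = v[4],
                   n = sum(v), nExcluded = 0L), class = "QuadrantCounts")
  }
  set.seed(33)
  for (rep in 1:10) {
    v <- sample(1:30, 4L, replace = TRUE)
    k <- sample(2:5, 1L)
    a <- implicationStatistic(mk(v))
    b <- implicationStatistic(mk(k * v))
    expect_equal(b$statistic, sqrt(k) * a$statistic)
    expect_equal(b$errorRate, a$errorRate)
  }
})

test_that("the partner search ranks a planted partner first", {
  cfg <- studyConfig(nCRC = 500L, nPolyp = 10L, nIBD = 40L, nNormal = 40L,
                     nGenes = 200L, nBimodal = 20L)
  study <- generateExpression(cfg, 301)
  cs <- thresholdAllGenes(study$se, margin = 0.5)
  res <- searchPartners(cs, cfg$targetGene, population = crcSamples(cs))
  expect_identical(res$gene[1L], cfg$markerGene)
  expect_true(res$passes[1L])
  expect_gt(res$statistic[1L], 3)
  expect_lt(res$errorRate[1L], 0.1)
  ## support fraction relative to the CRC population
  expect_true(all(res$supportFraction >= 0 & res$supportFraction <= 1))

  ## minN larger than the population empties the result list
  resEmpty <- searchPartners(cs, cfg$targetGene,
                             population = crcSamples(cs), minN = 10000L)
  expect_equal(nrow(resEmpty), 0L)
  expect_error(searchPartners(cs, "absent-gene"), "absent-gene")
})

test_that("independent genes rarely pass at the default thresholds", {
  for (seed in 1:5) {
    cfg <- studyConfig(nCRC = 200L, nPolyp = 0L, nIBD = 0L, nNormal = 0L,
                       nGenes = 100L, nBimodal = 30L,
                       plantImplication = FALSE)
    study <- generateExpression(cfg, seed)
    cs <- thresholdAllGenes(study$se, margin = 0.5)
    ## pick a bimodal gene as target so the search has usable calls
    res <- searchPartners(cs, study$truth$bimodalGenes[1L])
    expect_lte(sum(res$passes), 1L)
  }
})

test_that("permutation FDR is deterministic given a seed and 1 when nothing passes", {
  cfg <- studyConfig(nCRC = 150L, nPolyp = 0L, nIBD = 0L, nNormal = 0L,
                     nGenes = 50L, nBimodal = 10L, plantImplication = FALSE)
  study <- generateExpression(cfg, 5)
  cs <- thresholdAllGenes(study$se, margin = 0.5)
  target <- study$truth$bimodalGenes[1L]
  f1 <- estimateFDR(cs, target, nPerm = 20L, seed = 99L)
  f2 <- estimateFDR(cs, target, nPerm = 20L, seed = 99L)
  expect_identical(f1, f2)
  if (f1$observed == 0) expect_equal(f1$fdr, 1.0)

  ## several threshold configurations share one permutation set
  fm <- estimateFDR(cs, target, sMin = c(2, 3), errMax = c(0.2, 0.1),
                    nPerm = 10L, seed = 1L)
  expect_equal(nrow(fm), 2L)
})

test_that("a planted pair reaches a small permutation FDR", {
  cfg <- studyConfig(nCRC = 400L, nPolyp = 0L, nIBD = 0L, nNormal = 0L,
                     nGenes = 150L, nBimodal = 15L)
  study <- generateExpression(cfg, 77)
  cs <- thresholdAllGenes(study$se, margin = 0.5)
  fdr <- estimateFDR(cs, cfg$targetGene, nPerm = 50L, seed = 3L)
  expect_gte(fdr$observed, 1)
  expect_lt(fdr$fdr, 0.005)
})
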