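test_that("the generator is fully deterministic under a fixed seed", {
  a <- generateCohort(smallSyntheticConfig(seed = 3))
  b <- generateCohort(smallSyntheticConfig(seed = 3))
  expect_identical(a$cohort@weights, b$cohort@weights)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$truth@vulnerableNodes, b$truth@vulnerableNodes)
  c <- generateCohort(smallSyntheticConfig(seed = 4))
  expect_false(identical(a$cohort@weights, c$cohort@weights))
})

test_that("the edge template hits the density target and is seed-stable", {
  cfg <- syntheticConfig(seed = 5)
  t1 <- buildEdgeTemplate(cfg)
  t2 <- buildEdgeTemplate(cfg)
  expect_identical(t1$weights, t2$weights)
  for (seed in 1:5) {
    tpl <- buildEdgeTemplate(cfg, seed = seed)
    dens <- mean(tpl$weights[upper.tri(tpl$weights)] > 0)
    expect_lt(abs(dens - cfg$density), 0.02 + 0.01)  # target +- sampling
  }
  # scalar maps live on the weight support
  expect_identical(t1$gfa > 0, t1$weights > 0)
  expect_true(all(t1$gfa[t1$weights > 0] >= 0 &
                    t1$gfa[t1$weights > 0] <= 1))
  expect_true(all(t1$adc[t1$weights > 0] > 0))
})

test_that("generated cohorts satisfy the connectome invariants", {
  g <- generateCohort(smallSyntheticConfig(seed = 6))
  expect_true(validObject(g$cohort))
  for (i in c(1, nSubjects(g$cohort))) {
    con <- getConnectome(g$cohort, i)
    expect_true(validObject(con))
    expect_true(isSymmetric(con@weights))
    expect_true(all(diag(con@weights) == 0))
    expect_true(all(con@weights == round(con@weights)))
    expect_identical(is.na(con@gfa), con@weights == 0)
    expect_identical(is.na(con@adc), con@weights == 0)
  }
  # default group sizes mirror the reference cohort
  d <- syntheticConfig()
  expect_equal(unname(d$groupSizes),
               c(76, 25, 17, 17, 12))
  expect_equal(sum(d$groupSizes), 147)
})

test_that("a null configuration produces no systematic group differences", {
  gaps <- vapply(101:104, function(seed) {
    cfg <- smallSyntheticConfig(seed = seed, deltaMax = 0,
                                stageProfiles = FALSE, gfaDelta = 0,
                                adcDelta = 0, cognitionBeta = 0,
                                speedShifts = c(HC = 0, II = 0, IIIa = 0,
                                                IIIb = 0, IIIc = 0))
    g <- generateCohort(cfg)
    tot <- subnetworkStrengths(g$cohort,
                               seq_len(nRegions(g$cohort)))$total_strength
    g3 <- collapseStages(g$subjects$group, "ordered3")
    res <- residualize(tot, g$subjects[, c("age", "scanner")])
    abs(mean(res[g3 == "HC"]) - mean(res[g3 == "III"])) / stats::sd(res)
  }, 0)
  expect_lt(median(gaps), 0.6)  # small-n fixture; no consistent ordering
})

test_that("default effects order mean total strength HC > II > III", {
  set.seed(23)
  ok <- 0
  for (sd in 1:5) {
    g <- generateCohort(syntheticConfig(seed = sd))
    tot <- subnetworkStrengths(g$cohort,
                               seq_len(nRegions(g$cohort)))$total_strength
    covs <- g$subjects[, c("age", "gender", "handedness", "scanner")]
    res <- residualize(tot, covs)
    g3 <- collapseStages(g$subjects$group, "ordered3")
    m <- tapply(res, g3, mean)
    ok <- ok + (m["HC"] > m["II"] && m["II"] > m["III"])
  }
  expect_gte(ok, 4)
})

test_that("increasing the stage effect strictly lowers vulnerable-internal weights", {
  mean_vuln <- function(delta) {
    cfg <- smallSyntheticConfig(seed = 11, deltaMax = delta,
                                stageProfiles = FALSE)
    g <- generateCohort(cfg)
    st <- subnetworkStrengths(g$cohort, g$truth@vulnerableNodes)
    mean(st$vulnerable_strength[g$subjects$group %in%
                                  c("IIIa", "IIIb", "IIIc")])
  }
  v <- vapply(c(0, 0.15, 0.4), mean_vuln, 0)
  expect_gt(v[1], v[2])
  expect_gt(v[2], v[3])
})

test_that("truth report scores oracle and degenerate scans correctly", {
  g <- generateCohort(smallSyntheticConfig(seed = 8))
  n <- nRegions(g$cohort)
  oracleScan <- function(sel) {
    tab <- data.frame(node = seq_len(n), label = g$cohort@atlas$label,
                      statistic = 0, p = ifelse(seq_len(n) %in% sel, 0.01, 0.5),
                      vulnerable = seq_len(n) %in% sel,
                      fdr_significant = FALSE, stringsAsFactors = FALSE)
    new("TrendScanResult", table = tab, alpha = 0.05, fdrQ = 0.05,
        vulnerable = as.integer(sel), fdrSignificant = integer(0))
  }
  r <- truthReport(g$truth, scan = oracleScan(g$truth@vulnerableNodes))
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  # empty planted set: sensitivity undefined-flagged
  nullTruth <- new("SyntheticTruth", vulnerableNodes = integer(0),
                   stageProfiles = list(), cognitionRho = 0,
                   config = unclass(smallSyntheticConfig(seed = 8)))
  r0 <- truthReport(nullTruth, scan = oracleScan(c(1, 2)))
  expect_true(is.na(r0$sensitivity))
})

test_that("planted cognition coupling has the configured correlation scale", {
  cfg <- syntheticConfig(seed = 31)
  g <- generateCohort(cfg)
  expect_equal(g$truth@cognitionRho,
               cfg$cognitionBeta /
                 sqrt(cfg$cognitionBeta^2 + cfg$cognitionNoiseSd^2))
  # group means of the speed score approximate base - shift
  m <- tapply(g$subjects$processing_speed, g$subjects$group, mean)
  expect_equal(unname(m["HC"]), 53, tolerance = 3)
  expect_lt(m["IIIa"], m["HC"])
})
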