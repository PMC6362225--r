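test_that("consistency mask retains edges by presence fraction with >= rule", {
  w1 <- matrix(0, 3, 3); w1[1, 2] <- w1[2, 1] <- 1
  w2 <- w1; w2[1, 3] <- w2[3, 1] <- 2
  w3 <- w1; w4 <- w2
  cohort <- CohortConnectomes(list(w1, w2, w3, w4))
  mask <- consistencyMask(cohort, 0.5)
  # edge (1,2) present in 4/4, (1,3) in 2/4 (tie retained), (2,3) in 0/4
  expect_true(mask@retained[1, 2])
  expect_true(mask@retained[1, 3])
  expect_false(mask@retained[2, 3])
  expect_equal(mask@presenceFreq[1, 3], 0.5)
  # one subject only -> freq 0.25 at threshold 0.5 is discarded
  w5 <- matrix(0, 3, 3); w5[2, 3] <- w5[3, 2] <- 7
  mask2 <- consistencyMask(CohortConnectomes(list(w1, w1, w1, w5)), 0.5)
  expect_false(mask2@retained[2, 3])
  expect_equal(mask2@presenceFreq[2, 3], 0.25)
  expect_true(isSymmetric(mask@presenceFreq))
  expect_error(consistencyMask(cohort, 0), "threshold")
  expect_error(CohortConnectomes(list(w1, matrix(0, 4, 4))), "dimension")
})

test_that("applying a mask zeroes discarded edges, preserves symmetry, and is idempotent", {
  set.seed(5)
  w <- randomWeights(6, density = 0.8)
  g <- matrix(runif(36, 0.3, 0.7), 6, 6); g <- (g + t(g)) / 2
  con <- Connectome(w, gfa = g, subjectId = "a")
  retained <- w > 0
  retained[1, 2] <- retained[2, 1] <- FALSE
  freq <- retained * 1
  mask <- new("ConsistencyMask", retained = retained, threshold = 0.5,
              presenceFreq = freq)
  out <- applyMask(con, mask)
  expect_equal(out@weights[1, 2], 0)
  expect_equal(out@weights[2, 1], 0)
  expect_true(isSymmetric(out@weights))
  # gfa support equals weight support after masking
  expect_identical(is.na(out@gfa), out@weights == 0)
  # idempotence
  twice <- applyMask(out, mask)
  expect_identical(twice@weights, out@weights)
  # all-true mask is the identity transform
  allmask <- new("ConsistencyMask", retained = w > 0 | t(w) > 0,
                 threshold = 0.5, presenceFreq = (w > 0) * 1)
  expect_identical(applyMask(con, allmask)@weights, con@weights)
})

test_that("network measures match hand computations and conserve strength", {
  con <- triConnectome()
  m <- networkMeasures(con)
  expect_equal(m$nodal_strength, c(5, 7, 8))
  expect_equal(m$total_strength, 10)
  expect_equal(sum(m$nodal_strength), 2 * m$total_strength)
  # empty connectome
  e <- networkMeasures(Connectome(matrix(0, 4, 4)))
  expect_equal(e$nodal_strength, rep(0, 4))
  expect_equal(e$total_strength, 0)
  expect_true(is.na(e$mean_gfa))  # undefined, not zero
  # constant gfa on present edges -> mean 0.5 regardless of topology
  set.seed(2)
  w <- randomWeights(7, density = 0.5)
  g <- ifelse(w > 0, 0.5, 0)
  mg <- networkMeasures(Connectome(w, gfa = g))$mean_gfa
  expect_equal(mg, 0.5)
  # strength conservation on random fixtures
  for (s in 1:5) {
    w <- randomWeights(8, density = 0.4, seed = s)
    mm <- networkMeasures(Connectome(w))
    expect_equal(sum(mm$nodal_strength), 2 * mm$total_strength)
  }
})

test_that("tract-average scalars are invariant to consistent region permutation", {
  set.seed(9)
  w <- randomWeights(8, density = 0.5)
  g <- ifelse(w > 0, matrix(runif(64, 0.3, 0.7), 8, 8), NA)
  g[w > 0] <- (g + t(g))[w > 0] / 2
  a <- ifelse(w > 0, 8e-4, NA)
  con <- Connectome(w, gfa = g, adc = a)
  p <- sample(8)
  conP <- Connectome(w[p, p], gfa = g[p, p], adc = a[p, p])
  m1 <- networkMeasures(con); m2 <- networkMeasures(conP)
  expect_equal(m1$mean_gfa, m2$mean_gfa)
  expect_equal(m1$mean_adc, m2$mean_adc)
  expect_equal(m1$total_strength, m2$total_strength)
  expect_equal(m1$global_efficiency, m2$global_efficiency)
})

test_that("global efficiency matches hand-enumerated shortest paths", {
  # complete unit-weight graph
  w <- matrix(1, 4, 4); diag(w) <- 0
  expect_equal(globalEfficiency(Connectome(w)), 1)
  # 3-node path with unit weights: distances 1, 1, 2
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1; w[2, 3] <- w[3, 2] <- 1
  expect_equal(globalEfficiency(Connectome(w)), (1 + 1 + 0.5) / 3)
  # disconnected pair contributes zero
  w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 2
  expect_equal(globalEfficiency(Connectome(w)), (1 / (1 / 2)) * 2 / 6)
})

test_that("efficiency is monotone under edge removal at equal weights", {
  for (s in 1:6) {
    w <- randomWeights(7, density = 0.6, seed = 100 + s)
    full <- globalEfficiency(Connectome(w))
    on <- which(upper.tri(w) & w > 0)
    if (!length(on)) next
    drop <- sample(on, 1)
    w2 <- w
    w2[drop] <- 0
    w2 <- ifelse(upper.tri(w2), w2, 0); w2 <- w2 + t(w2)
    expect_lte(globalEfficiency(Connectome(w2)), full + 1e-12)
  }
})

test_that("weighted clustering matches triangle enumeration", {
  # equal-weight triangle: coefficient 1 at each node
  w <- matrix(5, 3, 3); diag(w) <- 0
  expect_equal(weightedClustering(Connectome(w)), rep(1, 3))
  # star graph: no triangles
  w <- matrix(0, 5, 5); w[1, 2:5] <- w[2:5, 1] <- 3
  expect_equal(weightedClustering(Connectome(w)), rep(0, 5))
  # random fixtures vs brute force
  for (s in 1:6) {
    w <- randomWeights(6, density = 0.6, seed = 200 + s)
    expect_equal(weightedClustering(Connectome(w)), bruteForceClustering(w),
                 tolerance = 1e-12)
  }
})

test_that("hub ranking flags dominant nodes and reports overlap", {
  # identical strengths -> no hubs
  w <- matrix(1, 5, 5); diag(w) <- 0
  cohort <- CohortConnectomes(list(w, w))
  hr <- hubRanking(cohort)
  expect_false(any(hr$hub))
  # one dominant node -> rank 1 and flagged
  w2 <- w; w2[1, -1] <- w2[-1, 1] <- 50
  cohort2 <- CohortConnectomes(list(w2, w2))
  hr2 <- hubRanking(cohort2)
  expect_equal(hr2$node[1], 1)
  expect_true(hr2$hub[1])
  ov <- nodeSetOverlap(hr2$node[hr2$hub], c(1, 3))
  expect_equal(ov$count, 1)
  expect_equal(ov$fraction, 1)
})

test_that("connectome validity rejects malformed inputs", {
  w <- matrix(0, 3, 3); w[1, 2] <- 1  # asymmetric
  expect_error(Connectome(w), "symmetric")
  w2 <- diag(3)
  expect_error(Connectome(w2), "diagonal")
  w3 <- matrix(0, 3, 3); w3[1, 2] <- w3[2, 1] <- -1
  expect_error(Connectome(w3), "nonnegative")
})

test_that("default atlas has the expected composition", {
  a <- regionAtlas()
  expect_equal(nrow(a), 82)
  expect_equal(sum(a$tissue_class == "cortical"), 68)
  expect_equal(sum(a$tissue_class == "subcortical"), 14)
  expect_false(anyDuplicated(a$label) > 0)
})
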