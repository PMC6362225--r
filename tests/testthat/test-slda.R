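toyClasses <- function(n = 60, p = 5, K = 3, sep = 2, seed = 42) {
  set.seed(seed)
  mu <- matrix(rnorm(K * p, sd = sep), K, p)
  cl <- rep(seq_len(K), each = n / K)
  X <- mu[cl, ] + matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, labels = factor(c("II", "IIIa", "IIIb", "IIIc")[cl]))
}

test_that("feature standardization stores parameters and drops constants", {
  toy <- toyClasses()
  fm <- standardizeFeatures(toy$X, toy$labels)
  expect_equal(unname(colMeans(fm$values)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(fm$values, 2, sd)), rep(1, 5), tolerance = 1e-12)
  # already standardized input: identity up to tolerance
  fm2 <- standardizeFeatures(fm$values, toy$labels)
  expect_equal(fm2$values, fm$values, tolerance = 1e-10,
               ignore_attr = TRUE)
  # constant column dropped with a warning
  Xc <- cbind(toy$X, flat = 1)
  expect_warning(fmc <- standardizeFeatures(Xc, toy$labels), "flat")
  expect_false("flat" %in% fmc$featureNames)
  expect_equal(fmc$dropped, "flat")
  expect_error(standardizeFeatures(toy$X[1:3, ], factor(c("a", "b", "b"))),
               "2 subjects")
})

test_that("a separable two-class problem selects the informative feature", {
  set.seed(7)
  X <- cbind(sig = c(rnorm(20, -3), rnorm(20, 3)),
             matrix(rnorm(40 * 4), 40, 4,
                    dimnames = list(NULL, paste0("n", 1:4))))
  lab <- factor(rep(c("a", "b"), each = 20))
  fit <- fitSparseDiscriminant(X, lab, budget = 2)
  expect_equal(ncol(fit@beta), 1)
  expect_equal(rownames(fit@beta)[which.max(abs(fit@beta[, 1]))], "sig")
  expect_lte(sum(fit@beta != 0), 2)
  ev <- loocvEvaluate(X, lab, budget = 2)
  expect_equal(ev@loocvError, 0)
  expect_equal(unname(diag(ev@confusion)), c(100, 100))
})

test_that("unpenalized optimal scoring spans the classical LDA subspace", {
  for (seed in c(42, 43)) {
    toy <- toyClasses(seed = seed)
    fit <- fitSparseDiscriminant(toy$X, toy$labels, lambda = 1e-8,
                                 budget = ncol(toy$X))
    V <- classicalLDAdirs(toy$X, toy$labels)
    expect_lt(max(principalAngles(fit@beta, V)), 1e-3)
  }
})

test_that("the fit is deterministic and respects its structural invariants", {
  toy <- toyClasses(n = 80, p = 8, K = 4)
  f1 <- fitSparseDiscriminant(toy$X, toy$labels, budget = 4)
  f2 <- fitSparseDiscriminant(toy$X, toy$labels, budget = 4)
  expect_identical(f1@beta, f2@beta)
  expect_equal(ncol(f1@beta), nlevels(toy$labels) - 1)  # Q = K - 1
  expect_true(all(colSums(f1@beta != 0) <= 4))
  # theta columns orthonormal in the class-proportion inner product
  pi <- as.vector(table(toy$labels)) / length(toy$labels)
  Gram <- t(f1@theta) %*% diag(pi) %*% f1@theta
  expect_equal(Gram, diag(ncol(f1@theta)), tolerance = 1e-6,
               ignore_attr = TRUE)
  # sign convention: dominant loading positive
  expect_true(all(apply(f1@beta, 2, function(b) b[which.max(abs(b))]) >= 0))
})

test_that("projection reproduces training centroids and handles zero columns", {
  toy <- toyClasses()
  fit <- fitSparseDiscriminant(toy$X, toy$labels, budget = 3)
  sc <- projectScores(fit, toy$X)
  cent <- apply(sc, 2, function(s) tapply(s, toy$labels, mean))
  expect_equal(unname(cent), unname(fit@centroids), tolerance = 1e-10)
  z <- fit
  z@beta[, 2] <- 0
  expect_equal(unname(projectScores(z, toy$X)[, 2]),
               rep(0, nrow(toy$X)))
  expect_error(projectScores(fit, toy$X[, 1:2]), "feature columns")
})

test_that("nearest-centroid classification breaks ties toward the first class", {
  centroids <- rbind(II = c(0, 0), IIIa = c(2, 0), IIIb = c(0, 2))
  expect_equal(as.character(nearestCentroidClassify(rbind(c(2, 0)),
                                                    centroids)), "IIIa")
  # equidistant from II and IIIa
  expect_equal(as.character(nearestCentroidClassify(rbind(c(1, 0)),
                                                    centroids)), "II")
})

test_that("baseline errors reproduce the closed-form majority arithmetic", {
  lab <- rep(c("II", "IIIa", "IIIb", "IIIc"), c(25, 17, 17, 12))
  b <- baselineErrors(lab)
  expect_equal(b$chance, 0.75)
  expect_equal(b$naive, 46 / 71)  # = 1 - 25/71, majority stable under deletion
  expect_equal(baselineErrors(rep("x", 10))$naive, 0)
  # generic-LOOCV naive equals 1 - n_majority/n for a stable unique majority
  set.seed(13)
  for (rep in 1:5) {
    sz <- sort(sample(3:9, 3), decreasing = TRUE)
    if (sz[1] <= sz[2] + 1) sz[1] <- sz[2] + 2
    lab2 <- rep(letters[1:3], sz)
    expect_equal(baselineErrors(lab2)$naive, 1 - sz[1] / sum(sz))
  }
})

test_that("LOOCV error sits at chance for permuted labels", {
  set.seed(17)
  toy <- toyClasses(n = 48, p = 5, K = 4, sep = 2)
  labP <- sample(toy$labels)
  ev <- suppressWarnings(loocvEvaluate(toy$X, labP, budget = 5))
  expect_gt(ev@loocvError, 0.5)   # Monte-Carlo band around 0.75
  expect_lt(ev@loocvError, 0.95)
  expect_equal(unname(rowSums(ev@confusion)), rep(100, 4), tolerance = 0.5)
})

test_that("interclass distances follow centroid geometry", {
  same <- matrix(1, 3, 2)
  d0 <- interclassDistances(same)
  expect_true(all(d0$distance_matrix == 0))
  # unit 3-simplex corners: all pairwise distances sqrt(2)
  corners <- diag(3)
  d1 <- interclassDistances(corners)
  off <- d1$distance_matrix[upper.tri(d1$distance_matrix)]
  expect_equal(off, rep(sqrt(2), 3))
  expect_equal(unname(d1$avg_distance), rep(sqrt(2), 3))
})

test_that("LDD clinical correlations report one row per direction and variable", {
  set.seed(19)
  scores <- matrix(rnorm(60), 20, 3)
  subjects <- data.frame(doi = rnorm(20, 3), processing_speed = rnorm(20, 45))
  tab <- lddClinicalCorrelations(scores, subjects)
  expect_equal(nrow(tab), 6)
  expect_setequal(tab$variable, c("doi", "processing_speed"))
  # a planted gradient is picked up
  subjects$doi <- -2 * scores[, 1] + rnorm(20, sd = 0.5)
  tab2 <- lddClinicalCorrelations(scores, subjects)
  expect_lt(tab2$r[tab2$ldd == 1 & tab2$variable == "doi"], -0.8)
})
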