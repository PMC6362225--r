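test_that("residualization is orthogonal to the covariates", {
  set.seed(3)
  n <- 60
  covs <- data.frame(age = rnorm(n, 26, 5),
                     gender = sample(c("M", "F"), n, TRUE),
                     handedness = sample(c("R", "L"), n, TRUE),
                     scanner = sample(c("pre", "post"), n, TRUE))
  y <- 2 * covs$age + rnorm(n)
  r <- residualize(y, covs)
  expect_lt(abs(cor(r, covs$age)), 1e-10)
  X <- covariateDesign(covs)
  expect_true(all(abs(crossprod(X, r)) < 1e-8))
  expect_equal(mean(r), 0, tolerance = 1e-12)
  # covariate orthogonal to y by construction -> residuals = y - mean(y)
  y2 <- rnorm(n)
  x0 <- data.frame(flat = rep(c(-1, 1), n / 2))
  y2 <- y2 - mean(y2[x0$flat == 1]) * (x0$flat == 1) -
    mean(y2[x0$flat == -1]) * (x0$flat == -1)
  expect_equal(residualize(y2, x0), y2 - mean(y2), tolerance = 1e-10)
})

test_that("rank-deficient covariate designs are rejected with the column named", {
  set.seed(4)
  covs <- data.frame(age = rnorm(20), age2 = NA)
  covs$age2 <- 2 * covs$age
  expect_error(residualize(rnorm(20), covs), "age2")
})

test_that("Cohen's d on residuals follows the pooled-SD convention", {
  expect_equal(cohensD(c(1, 2, 3), c(1, 2, 3)), 0)
  # pooled SD of {1,2,3} and {2,3,4} is 1
  expect_equal(cohensD(c(1, 2, 3), c(2, 3, 4)), -1)
  # invariance under a common affine transform
  a <- rnorm(10); b <- rnorm(12, 1)
  expect_equal(cohensD(a, b), cohensD(3 * a + 7, 3 * b + 7),
               tolerance = 1e-12)
  expect_true(is.na(cohensD(rep(1, 5), rep(2, 5))))
})

test_that("covariate-adjusted group effect recovers planted shifts", {
  set.seed(11)
  # identical data in both groups after adjustment: zero effect by symmetry
  n <- 80
  age <- rnorm(n / 2, 26, 5)
  covs <- data.frame(age = rep(age, 2))
  g <- factor(rep(c("HC", "EPP"), each = n / 2), levels = c("HC", "EPP"))
  y <- rep(1.5 * age + rnorm(n / 2, sd = 0.8), 2)
  eff <- ancovaGroupEffect(y, g, covs)
  expect_equal(eff$cohens_d, 0, tolerance = 1e-10)
  expect_equal(eff$p_value, 1, tolerance = 1e-10)
  # planted 1-SD shift, n = 50/50: median recovered d within 0.25 of 1
  ds <- replicate(100, {
    y <- c(rnorm(50, 1), rnorm(50, 0))
    ancovaGroupEffect(y, factor(rep(c("a", "b"), each = 50),
                                levels = c("a", "b")))$cohens_d
  })
  expect_lt(abs(median(ds) - 1), 0.25)
  # sign convention: first-listed group minus second
  y <- c(rnorm(50, 1), rnorm(50, 0))
  expect_gt(ancovaGroupEffect(y, factor(rep(c("HC", "EPP"), each = 50),
                                        levels = c("HC", "EPP")))$cohens_d, 0)
})

test_that("JT statistic and exact p match the worked example and Mann-Whitney", {
  jt <- jonckheereTerpstra(list(c(1, 2), c(3, 4), 5))
  expect_equal(jt$statistic, 8)  # its maximum
  expect_equal(jt$p_value, 1 / 30)
  expect_equal(jt$method, "exact")
  # two groups: statistic equals the Mann-Whitney exceedance count
  set.seed(21)
  a <- rnorm(8); b <- rnorm(9)
  jt2 <- jonckheereTerpstra(list(a, b))
  expect_equal(jt2$statistic,
               unname(wilcox.test(b, a, exact = FALSE)$statistic))
  # decreasing alternative is the reversed-order increasing test
  jt3 <- jonckheereTerpstra(list(5, c(3, 4), c(1, 2)),
                            direction = "decreasing")
  expect_equal(jt3$p_value, 1 / 30)
  # constant data: degenerate convention
  expect_equal(jonckheereTerpstra(list(c(1, 1), c(1, 1)))$p_value, 0.5)
  expect_error(jonckheereTerpstra(list(numeric(0), 1)), "at least one")
})

test_that("JT exact p equals exhaustive relabeling enumeration on small data", {
  set.seed(31)
  for (rep in 1:8) {
    sizes <- sample(2:3, sample(2:3, 1), replace = TRUE)
    samples <- lapply(sizes, function(k) sample(1:4, k, replace = TRUE))
    if (length(unique(unlist(samples))) == 1L) next
    jt <- jonckheereTerpstra(samples)
    expect_equal(jt$p_value, jtExactOracle(samples), tolerance = 1e-12)
  }
})

test_that("JT normal approximation tracks the permutation null at n=(10,10,10)", {
  set.seed(41)
  for (rep in 1:5) {
    samples <- lapply(1:3, function(i) rnorm(10, mean = 0.15 * i) +
                        sample(0:1, 10, TRUE) * 0.5)
    asym <- jonckheereTerpstra(samples, enumerationCap = 1)
    expect_equal(asym$method, "asymptotic")
    mc <- jtMCOracle(samples, B = 4000, seed = 500 + rep)
    expect_lt(abs(asym$p_value - mc), 0.025)
  }
})

test_that("BH step-up flags match the literal definition", {
  r <- bhFdr(c(0.01, 0.02, 0.04, 0.2), q = 0.05)
  expect_identical(r$significant, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$adjusted, c(0.04, 0.04, 0.04 * 4 / 3, 0.2))
  expect_true(bhFdr(0.01, 0.05)$significant)
  expect_length(bhFdr(numeric(0))$adjusted, 0)
  set.seed(51)
  for (rep in 1:50) {
    p <- round(runif(sample(1:6, 1)), 3)
    expect_identical(bhFdr(p, 0.05)$significant, stepUpBH(p, 0.05))
  }
})

test_that("Pearson correlation handles exact and planted cases", {
  x <- rnorm(20)
  expect_equal(pearsonCorrelation(x, x)$r, 1)
  expect_equal(pearsonCorrelation(x, -x + 3)$r, -1)
  expect_true(is.na(pearsonCorrelation(x, rep(1, 20))$r))
  set.seed(61)
  est <- replicate(200, {
    z <- rnorm(76)
    x <- z
    y <- 0.4 * z + sqrt(1 - 0.16) * rnorm(76)
    pearsonCorrelation(x, y)$r
  })
  expect_lt(abs(mean(est) - 0.4), 0.05)
})

test_that("chi-square and one-way ANOVA reproduce the printed cohort table", {
  # gender HC vs EPP
  expect_equal(chiSquareContingency(rbind(c(48, 28), c(49, 22)))$p, 0.45,
               tolerance = 0.01)
  # handedness II vs III
  h <- chiSquareContingency(rbind(c(25, 0), c(39, 7)))
  expect_equal(round(h$chi2, 2), 4.22)
  expect_equal(round(h$p, 3), 0.040)
  # proportional table: exact independence
  pr <- chiSquareContingency(rbind(c(10, 10), c(20, 20)))
  expect_equal(pr$chi2, 0)
  expect_equal(pr$p, 1)
  expect_error(chiSquareContingency(rbind(c(0, 0), c(1, 2))), "margin")
  # ANOVA from printed summaries
  expect_equal(onewayAnova(data.frame(n = c(76, 71), mean = c(26.8, 26.0),
                                      sd = c(6.1, 6.2)))$p, 0.43,
               tolerance = 0.01)
  # equal group means
  eq <- onewayAnova(list(c(1, 2, 3), c(2, 1, 3)))
  expect_equal(eq$F, 0)
  expect_equal(eq$p, 1)
})

test_that("ANOVA summary mode equals raw mode exactly", {
  set.seed(71)
  for (rep in 1:5) {
    gs <- lapply(sample(3:6, 3, TRUE) + 2, rnorm)
    raw <- onewayAnova(gs)
    summ <- onewayAnova(data.frame(n = lengths(gs),
                                   mean = vapply(gs, mean, 0),
                                   sd = vapply(gs, sd, 0)))
    expect_equal(raw$F, summ$F, tolerance = 1e-10)
    expect_equal(raw$p, summ$p, tolerance = 1e-10)
  }
})

test_that("logistic impairment models rank planted deficits correctly", {
  set.seed(81)
  status <- rep(c("HC", "EPP"), c(76, 71))
  # identical distributions -> OR near 1
  or0 <- replicate(40, {
    logisticDomainImpairment(rnorm(147), status)$odds_ratio
  })
  expect_lt(abs(median(log(or0))), 0.3)
  # planted 1-SD deficit in patients: direction correct in >= 95% of fits
  hits <- replicate(200, {
    sc <- c(rnorm(76, 0), rnorm(71, -1))
    logisticDomainImpairment(sc, status)$odds_ratio < 1
  })
  expect_gte(mean(hits), 0.95)
  # most-shifted domain ranks first
  sc <- cbind(speed = c(rnorm(76), rnorm(71, -1.5)),
              memory = c(rnorm(76), rnorm(71, -0.3)))
  expect_equal(logisticDomainImpairment(sc, status)$domain[1], "speed")
  # complete separation is flagged, not fatal
  sep <- logisticDomainImpairment(c(rnorm(76, 5), rnorm(71, -5)), status)
  expect_true(sep$separation)
  expect_true(is.finite(sep$p))
})
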