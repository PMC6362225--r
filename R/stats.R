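.FACTOR_LEVELS <- list(
  gender = c("F", "M"), handedness = c("L", "R"), scanner = c("pre", "post"),
  group = c("HC", "II", "IIIa", "IIIb", "IIIc")
)

#' Default covariate design matrix
#'
#' Codes the standard covariate set (age, gender, handedness,
#' scanner-upgrade flag) as a numeric design matrix without intercept.
#' Categorical covariates become 0/1 indicators with fixed reference levels:
#' female, left-handed, pre-upgrade.
#'
#' @param covariates \code{data.frame} of covariate columns; character or
#'   factor columns are indicator-coded, numeric columns passed through.
#' @return numeric matrix, one column per coded covariate.
#' @export
covariateDesign <- function(covariates) {
  covariates <- as.data.frame(covariates)
  cols <- lapply(names(covariates), function(nm) {
    v <- covariates[[nm]]
    if (is.numeric(v)) {
      m <- matrix(v, ncol = 1, dimnames = list(NULL, nm))
    } else {
      lev <- .FACTOR_LEVELS[[nm]]
      f <- factor(v, levels = if (is.null(lev)) sort(unique(as.character(v)))
                  else lev)
      if (any(is.na(f))) stop(sprintf("invalid levels in covariate '%s'", nm))
      ind <- stats::model.matrix(~ f)[, -1, drop = FALSE]
      colnames(ind) <- paste0(nm, levels(f)[-1])
      m <- ind
    }
    m
  })
  do.call(cbind, cols)
}

.dropConstantColumns <- function(X) {
  keep <- apply(X, 2, function(col) length(unique(col)) > 1L)
  X[, keep, drop = FALSE]
}

#' Residualize values on covariates
#'
#' Least-squares regression of \code{y} on an intercept plus the covariates
#' (no group term); the returned residuals are exactly orthogonal to every
#' covariate column. This is the adjustment step used before effect sizes and
#' trend tests throughout the package. Covariate columns that are constant in
#' the analyzed subset (e.g. handedness in a right-handers-only re-analysis)
#' carry no information and are dropped.
#'
#' @param y numeric vector of per-subject values.
#' @param covariates \code{data.frame} or numeric matrix of covariates; see
#'   [covariateDesign()].
#' @return numeric vector of residuals.
#' @examples
#' age <- rnorm(40, 25, 5)
#' y <- 2 * age + rnorm(40)
#' r <- residualize(y, data.frame(age = age))
#' cor(r, age)  # ~0
#' @export
residualize <- function(y, covariates) {
  X <- if (is.matrix(covariates)) covariates else covariateDesign(covariates)
  if (anyNA(X) || anyNA(y)) stop("covariates and values must be complete")
  X <- .dropConstantColumns(X)
  if (ncol(X) == 0L) return(y - mean(y))
  X1 <- cbind(`(Intercept)` = 1, X)
  qr1 <- qr(X1)
  if (qr1$rank < ncol(X1)) {
    bad <- colnames(X1)[qr1$pivot[(qr1$rank + 1):ncol(X1)]]
    stop(sprintf("rank-deficient covariate design; collinear columns: %s",
                 paste(bad, collapse = ", ")))
  }
  unname(stats::lm.fit(X1, y)$residuals)
}

#' Cohen's d between residual distributions
#'
#' Standardized mean difference (first sample minus second) in pooled-SD
#' units with (n_a - 1, n_b - 1) weighting, computed on covariate-adjusted
#' residuals.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @return signed scalar d; \code{NA} when the pooled SD is zero.
#' @export
cohensD <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("each sample needs >= 2 values")
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 <= 0) return(NA_real_)
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Covariate-adjusted group effect (ANCOVA)
#'
#' Fits the general linear model \code{y ~ group + covariates} and reports
#' the F-test p-value for the group factor. The effect size is Cohen's d
#' between the covariate-only residual distributions of the two groups
#' (two-step: [residualize()] then [cohensD()]), signed as first-listed group
#' minus second.
#'
#' @param y numeric per-subject values.
#' @param group factor or character of group labels; the d is reported for
#'   the first two levels.
#' @param covariates covariate \code{data.frame} (may be \code{NULL}).
#' @return a list with \code{p_value}, \code{cohens_d}, \code{group_sizes},
#'   \code{residuals}.
#' @export
ancovaGroupEffect <- function(y, group, covariates = NULL) {
  group <- if (is.factor(group)) droplevels(group) else
    factor(group, levels = unique(group))
  if (nlevels(group) < 2L) stop("need at least two groups")
  if (any(table(group) < 2L)) stop("each group needs >= 2 subjects")
  X <- if (is.null(covariates)) NULL else
    .dropConstantColumns(covariateDesign(covariates))
  if (!is.null(X) && ncol(X) == 0L) X <- NULL
  dat <- data.frame(y = y, group = group)
  # covariates enter first so the sequential F-test of the group term is
  # adjusted for them
  fit <- if (is.null(X)) stats::lm(y ~ group, data = dat) else
    stats::lm(y ~ X + group, data = dat)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop(sprintf("confounded design, inestimable terms: %s",
                 paste(bad, collapse = ", ")))
  }
  av <- stats::anova(fit)
  p <- av[["Pr(>F)"]][rownames(av) == "group"]
  res <- if (is.null(X)) y - mean(y) else residualize(y, X)
  l12 <- levels(group)[1:2]
  d <- cohensD(res[group == l12[1]], res[group == l12[2]])
  list(p_value = p, cohens_d = d, group_sizes = as.integer(table(group)),
       residuals = res)
}

.jtStatistic <- function(values, g) {
  # g: integer group index in the hypothesized increasing order
  ng <- max(g)
  stat <- 0
  for (a in seq_len(ng - 1L)) for (b in seq.int(a + 1L, ng)) {
    xa <- values[g == a]
    xb <- values[g == b]
    cmp <- outer(xa, xb, "<")
    ties <- outer(xa, xb, "==")
    stat <- stat + sum(cmp) + 0.5 * sum(ties)
  }
  stat
}

.jtNullMoments <- function(values, sizes) {
  N <- sum(sizes)
  t <- as.vector(table(values))
  mu <- (N^2 - sum(sizes^2)) / 4
  v1 <- (N * (N - 1) * (2 * N + 5) -
           sum(sizes * (sizes - 1) * (2 * sizes + 5)) -
           sum(t * (t - 1) * (2 * t + 5))) / 72
  v2 <- sum(sizes * (sizes - 1) * (sizes - 2)) *
    sum(t * (t - 1) * (t - 2)) / (36 * N * (N - 1) * (N - 2))
  v3 <- sum(sizes * (sizes - 1)) * sum(t * (t - 1)) / (8 * N * (N - 1))
  list(mean = mu, var = max(v1 + v2 + v3, 0))
}

.jtEnumerate <- function(values, sizes, observed) {
  # exact one-sided p over all distinct assignments of the pooled values to
  # groups of the given sizes: P(T >= observed)
  count <- 0L
  total <- 0L
  recurse <- function(idx, g) {
    if (g > length(sizes)) {
      lab <- integer(length(values))
      for (k in seq_along(idx)) lab[idx[[k]]] <- k
      s <- .jtStatistic(values, lab)
      total <<- total + 1L
      if (s >= observed - 1e-9) count <<- count + 1L
      return(invisible())
    }
    remaining <- setdiff(seq_along(values), unlist(idx))
    if (sizes[g] == length(remaining)) {
      recurse(c(idx, list(remaining)), g + 1L)
    } else {
      ch <- utils::combn(remaining, sizes[g])
      for (j in seq_len(ncol(ch))) recurse(c(idx, list(ch[, j])), g + 1L)
    }
  }
  recurse(list(), 1L)
  list(p = count / total, n_perm = total)
}

#' Jonckheere-Terpstra test for ordered alternatives
#'
#' Tests a monotone trend across two or more groups given in a stated order.
#' The statistic is the sum over ordered group pairs of pairwise exceedance
#' counts, with ties contributing one half. For a \code{"decreasing"}
#' alternative the group order is reversed before counting. The one-sided
#' p-value is exact (complete enumeration of group-label assignments) when
#' the number of distinct assignments is at most \code{enumerationCap}, and
#' otherwise uses the tie-corrected normal approximation without continuity
#' correction. Fully constant data yield the degenerate convention p = 0.5.
#'
#' @param samples list of numeric vectors, one per group, in the
#'   hypothesized order.
#' @param direction \code{"increasing"} or \code{"decreasing"} alternative.
#' @param enumerationCap largest number of label assignments enumerated
#'   exactly (default 1e6).
#' @return a list with \code{statistic} (computed in the increasing
#'   orientation actually tested), \code{null_mean}, \code{null_sd},
#'   \code{p_value}, \code{method} (\code{"exact"}/\code{"asymptotic"}),
#'   \code{direction}.
#' @examples
#' jonckheereTerpstra(list(c(1, 2), c(3, 4), 5))$p_value  # 1/30
#' @export
jonckheereTerpstra <- function(samples,
                               direction = c("increasing", "decreasing"),
                               enumerationCap = 1e6) {
  direction <- match.arg(direction)
  sizes <- lengths(samples)
  if (any(sizes == 0L)) stop("every group needs at least one observation")
  if (length(samples) < 2L) stop("need at least two groups")
  ordered <- if (direction == "decreasing") rev(samples) else samples
  values <- unlist(ordered, use.names = FALSE)
  g <- rep(seq_along(ordered), lengths(ordered))
  stat <- .jtStatistic(values, g)
  mom <- .jtNullMoments(values, lengths(ordered))
  sd0 <- sqrt(mom$var)
  if (length(unique(values)) == 1L) {
    return(list(statistic = stat, null_mean = mom$mean, null_sd = 0,
                p_value = 0.5, method = "degenerate", direction = direction))
  }
  nPerm <- exp(lgamma(sum(sizes) + 1) - sum(lgamma(sizes + 1)))
  if (nPerm <= enumerationCap) {
    ex <- .jtEnumerate(values, lengths(ordered), stat)
    list(statistic = stat, null_mean = mom$mean, null_sd = sd0,
         p_value = ex$p, method = "exact", direction = direction)
  } else {
    z <- (stat - mom$mean) / sd0
    list(statistic = stat, null_mean = mom$mean, null_sd = sd0,
         p_value = stats::pnorm(z, lower.tail = FALSE),
         method = "asymptotic", direction = direction)
  }
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up procedure at level \code{q}: adjusted p-values via
#' \code{\link[stats]{p.adjust}(method = "BH")} and significance flags
#' \code{adjusted <= q}.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param q FDR level (default 0.05).
#' @return a list with \code{adjusted} and logical \code{significant}.
#' @export
bhFdr <- function(p, q = 0.05) {
  if (length(p) == 0L)
    return(list(adjusted = numeric(0), significant = logical(0)))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = "BH")
  list(adjusted = adj, significant = !is.na(adj) & adj <= q)
}

#' Pearson correlation with two-sided p
#'
#' @param x,y numeric vectors; pairs with missing values are dropped.
#' @return a list with \code{r}, \code{p}, \code{n}; \code{r = NA} when
#'   either variable is constant or fewer than 3 complete pairs remain.
#' @export
pearsonCorrelation <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(x)))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Pearson chi-square test of independence
#'
#' Without continuity correction, as used for the cohort's categorical
#' comparisons.
#'
#' @param counts matrix of nonnegative counts, at least 2 x 2.
#' @return a list with \code{chi2}, \code{df}, \code{p}.
#' @export
chiSquareContingency <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L) stop("table must be >= 2 x 2")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero row or column margin")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter), p = ct$p.value)
}

#' One-way ANOVA from raw samples or group summaries
#'
#' Raw mode takes a list of numeric vectors. Summary mode reconstructs the
#' between/within sums of squares from per-group (n, mean, sd) triplets, so
#' printed summary tables can be re-analyzed exactly.
#'
#' @param groups list of numeric vectors, or a \code{data.frame}/matrix with
#'   columns \code{n}, \code{mean}, \code{sd} (one row per group).
#' @return a list with \code{F}, \code{df1}, \code{df2}, \code{p}; \code{F}
#'   is \code{NA} when the within-group variance is zero.
#' @examples
#' onewayAnova(data.frame(n = c(76, 71), mean = c(26.8, 26.0),
#'                        sd = c(6.1, 6.2)))$p
#' @export
onewayAnova <- function(groups) {
  if (is.list(groups) && !is.data.frame(groups)) {
    n <- lengths(groups)
    m <- vapply(groups, mean, 0)
    s <- vapply(groups, stats::sd, 0)
  } else {
    groups <- as.data.frame(groups)
    n <- groups$n; m <- groups$mean; s <- groups$sd
  }
  if (length(n) < 2L) stop("need at least two groups")
  if (any(n < 2L)) stop("summary mode needs n >= 2 per group")
  N <- sum(n); k <- length(n)
  gm <- sum(n * m) / N
  ssb <- sum(n * (m - gm)^2)
  ssw <- sum((n - 1) * s^2)
  if (ssw <= 0) {
    if (ssb <= 0) return(list(F = NA_real_, df1 = k - 1, df2 = N - k,
                              p = NA_real_))
    return(list(F = Inf, df1 = k - 1, df2 = N - k, p = 0))
  }
  F <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = F, df1 = k - 1, df2 = N - k,
       p = stats::pf(F, k - 1, N - k, lower.tail = FALSE))
}

.ridgeLogistic <- function(X, y, ridge = 1e-4, maxit = 100, tol = 1e-8) {
  # IRLS with a small ridge on all coefficients except the intercept
  X1 <- cbind(1, X)
  beta <- rep(0, ncol(X1))
  pen <- c(0, rep(ridge, ncol(X)))
  ll0 <- -Inf
  for (it in seq_len(maxit)) {
    eta <- drop(X1 %*% beta)
    mu <- stats::plogis(eta)
    Wd <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X1, X1 * Wd) + diag(pen, ncol(X1))
    g <- crossprod(X1, y - mu) - pen * beta
    beta <- beta + solve(H, g)
    ll <- sum(y * eta - log1p(exp(eta))) - sum(pen * beta^2) / 2
    if (is.finite(ll0) && abs(ll - ll0) < tol * (abs(ll0) + 1)) break
    ll0 <- ll
  }
  eta <- drop(X1 %*% beta)
  mu <- stats::plogis(eta)
  Wd <- pmax(mu * (1 - mu), 1e-10)
  H <- crossprod(X1, X1 * Wd) + diag(pen, ncol(X1))
  se <- sqrt(diag(solve(H)))
  list(beta = beta, se = se)
}

#' Logistic models of cognitive-domain impairment
#'
#' Fits, per cognitive domain, a logistic regression of patient status on the
#' standardized domain score plus covariates, and ranks domains by the
#' magnitude of the per-SD log odds ratio. Complete separation is flagged and
#' handled by a small-ridge refit.
#'
#' @param scores numeric vector or subjects x domains matrix/data.frame of
#'   cognitive scores.
#' @param status factor/character with levels \code{HC} and \code{EPP} (or
#'   any two levels; the second is modeled as the event).
#' @param covariates optional covariate \code{data.frame}.
#' @return a \code{data.frame} ranked by \code{|log(OR)|} with columns
#'   \code{domain}, \code{odds_ratio} (per SD), \code{p}, \code{separation}.
#' @export
logisticDomainImpairment <- function(scores, status, covariates = NULL) {
  scores <- as.matrix(as.data.frame(scores))
  status <- factor(status)
  if (nlevels(status) != 2L) stop("status must have exactly two levels")
  if (is.factor(status) && all(c("HC", "EPP") %in% levels(status)))
    status <- factor(as.character(status), levels = c("HC", "EPP"))
  y <- as.integer(status == levels(status)[2])
  Xc <- if (is.null(covariates)) NULL else covariateDesign(covariates)
  rows <- lapply(seq_len(ncol(scores)), function(j) {
    z <- as.vector(scale(scores[, j]))
    X <- cbind(score = z, Xc)
    dat <- data.frame(y = y, X)
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm(y ~ ., data = dat, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities|did not converge", conditionMessage(w)))
          sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (sep || anyNA(stats::coef(fit))) {
      rf <- .ridgeLogistic(X, y)
      est <- rf$beta[2]; se <- rf$se[2]
      sep <- TRUE
    } else {
      sm <- summary(fit)$coefficients
      est <- sm["score", 1]; se <- sm["score", 2]
    }
    p <- 2 * stats::pnorm(-abs(est / se))
    data.frame(domain = colnames(scores)[j] %||% sprintf("domain%d", j),
               odds_ratio = exp(est), p = p, separation = sep,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-abs(log(out$odds_ratio))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
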