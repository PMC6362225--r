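# Independent oracles used to freeze expected values. These deliberately use
# different algorithms from the package implementation.

# all permutations of 1..n as an n! x n matrix (n <= 8)
allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- allPermutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- seq_len(nrow(sub)) + r
    out[rows, 1] <- k
    out[rows, -1] <- ifelse(sub >= k, sub + 1L, sub)
    r <- r + nrow(sub)
  }
  out
}

# pairwise-loop JT statistic (increasing alternative), independent of the
# package's group-pair outer() formulation
jtStatOracle <- function(values, groups) {
  n <- length(values)
  stat <- 0
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    if (groups[i] < groups[j]) {
      stat <- stat + (values[i] < values[j]) + 0.5 * (values[i] == values[j])
    } else if (groups[j] < groups[i]) {
      stat <- stat + (values[j] < values[i]) + 0.5 * (values[j] == values[i])
    }
  }
  stat
}

# exhaustive permutation p-value: P(T >= observed) over all n! relabelings
jtExactOracle <- function(samples) {
  values <- unlist(samples, use.names = FALSE)
  groups <- rep(seq_along(samples), lengths(samples))
  obs <- jtStatOracle(values, groups)
  perms <- allPermutations(length(values))
  stats <- apply(perms, 1, function(p) jtStatOracle(values[p], groups))
  mean(stats >= obs - 1e-9)
}

# Monte-Carlo permutation p-value for sizes where enumeration is infeasible
jtMCOracle <- function(samples, B = 20000, seed = 99) {
  set.seed(seed)
  values <- unlist(samples, use.names = FALSE)
  groups <- rep(seq_along(samples), lengths(samples))
  obs <- jtStatOracle(values, groups)
  hits <- 0L
  for (b in seq_len(B)) {
    s <- jtStatOracle(sample(values), groups)
    if (s >= obs - 1e-9) hits <- hits + 1L
  }
  hits / B
}

# literal step-up definition of Benjamini-Hochberg rejection flags
stepUpBH <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  k <- which(p[ord] <= q * seq_len(m) / m)
  reject <- logical(m)
  if (length(k)) reject[ord[seq_len(max(k))]] <- TRUE
  reject
}

# Floyd-Warshall shortest paths on inverse-weight lengths
bruteForceEfficiency <- function(w) {
  n <- nrow(w)
  if (n < 2) return(0)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[w > 0] <- 1 / w[w > 0]
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

# explicit triangle enumeration for the Onnela clustering coefficient
bruteForceClustering <- function(w) {
  n <- nrow(w)
  wh <- if (max(w) > 0) w / max(w) else w
  cc <- numeric(n)
  for (i in 1:n) {
    k <- sum(w[i, ] > 0)
    if (k < 2) next
    tot <- 0
    for (j in 1:n) for (h in 1:n) {
      if (j == i || h == i || j == h) next
      if (w[i, j] > 0 && w[i, h] > 0 && w[j, h] > 0)
        tot <- tot + (wh[i, j] * wh[i, h] * wh[j, h])^(1 / 3)
    }
    cc[i] <- tot / (k * (k - 1))
  }
  cc
}

# classical LDA discriminant directions by the generalized eigenproblem
# W^-1 B on column-standardized features
classicalLDAdirs <- function(X, labels) {
  Xs <- scale(X)
  labels <- factor(labels)
  p <- ncol(Xs); K <- nlevels(labels)
  gm <- colMeans(Xs)
  B <- matrix(0, p, p); W <- matrix(0, p, p)
  for (lv in levels(labels)) {
    idx <- labels == lv
    mk <- colMeans(Xs[idx, , drop = FALSE])
    B <- B + sum(idx) * tcrossprod(mk - gm)
    W <- W + crossprod(scale(Xs[idx, , drop = FALSE], center = mk,
                             scale = FALSE))
  }
  ev <- eigen(solve(W) %*% B)
  Re(ev$vectors[, seq_len(K - 1), drop = FALSE])
}

principalAngles <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  acos(pmin(svd(crossprod(qa, qb))$d, 1))
}

# random symmetric integer-weight connectome fixture
randomWeights <- function(n, density = 0.6, maxw = 9, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- matrix(0, n, n)
  up <- which(upper.tri(w))
  on <- up[runif(length(up)) < density]
  w[on] <- sample.int(maxw, length(on), replace = TRUE)
  w + t(w)
}
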