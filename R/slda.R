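#' Standardize nodal-strength features
#'
#' Column z-scoring with stored parameters for out-of-sample projection.
#' Constant columns carry no discriminative information under the penalized
#' fit and are dropped with a warning.
#'
#' @param x subjects x regions numeric matrix of nodal strengths.
#' @param labels per-subject class labels (factor or character); every class
#'   needs at least 2 subjects.
#' @return a list (feature matrix) with \code{values} (standardized),
#'   \code{center}, \code{scale}, \code{featureNames}, \code{labels},
#'   \code{dropped}.
#' @export
standardizeFeatures <- function(x, labels) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%03d", seq_len(ncol(x)))
  labels <- if (is.factor(labels)) droplevels(labels) else
    factor(labels, levels = unique(labels))
  if (nrow(x) != length(labels)) stop("labels do not match the feature rows")
  if (any(table(labels) < 2L)) stop("every class needs at least 2 subjects")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  keep <- scl > 0
  if (!all(keep))
    warning(sprintf("dropping %d constant feature column(s): %s",
                    sum(!keep),
                    paste(colnames(x)[!keep], collapse = ", ")))
  vals <- scale(x[, keep, drop = FALSE], center = ctr[keep],
                scale = scl[keep])
  attr(vals, "scaled:center") <- NULL
  attr(vals, "scaled:scale") <- NULL
  list(values = vals, center = ctr[keep], scale = scl[keep],
       featureNames = colnames(x)[keep], labels = labels,
       dropped = colnames(x)[!keep])
}

.enetSolve <- function(X, y, lambda, budget) {
  n <- nrow(X); p <- ncol(X)
  if (budget >= p) {
    A <- crossprod(X) / n + diag(lambda, p)
    return(drop(solve(A, crossprod(X, y) / n)))
  }
  # elastic net with fixed ridge as a lasso on ridge-augmented rows; the
  # sparsity budget picks the least-penalized path point with <= budget
  # nonzero loadings
  Xa <- rbind(X, diag(sqrt(n * lambda), p))
  ya <- c(y, rep(0, p))
  fit <- glmnet::glmnet(Xa, ya, alpha = 1, standardize = FALSE,
                        intercept = FALSE, nlambda = 35,
                        lambda.min.ratio = 1e-3, dfmax = budget)
  ok <- which(fit$df <= budget)
  j <- ok[length(ok)]
  drop(as.matrix(fit$beta[, j]))
}

.dpiOrthogonalize <- function(w, prev, pi) {
  # Gram-Schmidt under the class-proportion inner product <a,b> = sum pi*a*b
  for (k in seq_len(ncol(prev))) {
    w <- w - sum(pi * w * prev[, k]) * prev[, k]
  }
  nrm <- sqrt(sum(pi * w^2))
  if (nrm < 1e-12) return(NULL)
  w / nrm
}

#' Fit a sparse discriminant model by penalized optimal scoring
#'
#' Recasts linear discriminant analysis as a regression of optimal class
#' scores on the standardized features and solves it with an elastic-net
#' penalty, yielding Q = K - 1 sparse linear discriminant directions (LDDs).
#' For each direction the algorithm alternates (a) an elastic-net regression
#' of the scored class indicators on the features (ridge \code{lambda};
#' at most \code{budget} nonzero loadings, enforced on the lasso path) and
#' (b) an update of the score vector as the normalized projection of the
#' fitted scores onto the class indicators, kept orthogonal - in the
#' class-proportion inner product - to the constant vector and to previous
#' scores. Initialization is deterministic (leading singular vectors of the
#' class-mean matrix), so the fit is reproducible without a seed. Each beta
#' column's largest-magnitude loading is made positive.
#'
#' @param x features: either the list returned by [standardizeFeatures()] or
#'   a raw subjects x regions matrix (standardized internally).
#' @param labels class labels, required when \code{x} is a matrix.
#' @param lambda ridge penalty (default 1e-3).
#' @param budget maximum nonzero loadings per LDD (default 15); use
#'   \code{ncol(x)} for no sparsity constraint.
#' @param tol relative convergence tolerance of the alternating loop
#'   (default 1e-6).
#' @param maxit maximum alternating iterations per LDD (default 200).
#' @return a [SparseDiscriminantModel-class] object.
#' @export
fitSparseDiscriminant <- function(x, labels = NULL, lambda = 1e-3,
                                  budget = 15, tol = 1e-6, maxit = 200) {
  fm <- if (is.list(x) && !is.data.frame(x)) x else
    standardizeFeatures(x, labels)
  X <- fm$values
  labels <- fm$labels
  n <- nrow(X); p <- ncol(X)
  K <- nlevels(labels)
  if (K < 2L) stop("need at least two classes")
  Q <- K - 1L
  Y <- stats::model.matrix(~ labels - 1)
  colnames(Y) <- levels(labels)
  pi <- colMeans(Y)
  # deterministic initialization: leading singular vectors of the
  # proportion-weighted class-mean matrix
  M <- (t(Y) %*% X) / n / sqrt(pi)
  sv <- svd(M)
  theta0 <- sv$u / sqrt(pi)
  beta <- matrix(0, p, Q, dimnames = list(colnames(X), NULL))
  theta <- matrix(0, K, Q, dimnames = list(levels(labels), NULL))
  converged <- logical(Q)
  iterations <- integer(Q)
  ones <- matrix(1, K, 1)
  for (q in seq_len(Q)) {
    prev <- cbind(ones, theta[, seq_len(q - 1L), drop = FALSE])
    th <- NULL
    cand <- 0L
    while (is.null(th) && cand < K) {
      cand <- cand + 1L
      init <- if (cand <= ncol(theta0)) theta0[, cand] else
        as.numeric(seq_len(K) == cand)
      th <- .dpiOrthogonalize(init, prev, pi)
    }
    if (is.null(th)) stop("could not initialize the score vector")
    b <- rep(0, p)
    for (it in seq_len(maxit)) {
      b <- .enetSolve(X, drop(Y %*% th), lambda, budget)
      if (all(b == 0)) { converged[q] <- TRUE; iterations[q] <- it; break }
      s <- drop(X %*% b)
      w <- drop(crossprod(Y, s)) / n / pi
      w <- .dpiOrthogonalize(w, prev, pi)
      if (is.null(w)) { converged[q] <- TRUE; iterations[q] <- it; break }
      delta <- max(abs(w - th)) / max(1, max(abs(th)))
      th <- w
      iterations[q] <- it
      if (delta < tol) { converged[q] <- TRUE; break }
    }
    if (anyNA(b)) stop("sparse discriminant fit produced NaN loadings")
    theta[, q] <- th
    beta[, q] <- b
  }
  # sign convention: dominant loading positive per direction
  for (q in seq_len(Q)) {
    nz <- which.max(abs(beta[, q]))
    if (length(nz) && beta[nz, q] < 0) {
      beta[, q] <- -beta[, q]
      theta[, q] <- -theta[, q]
    }
  }
  scores <- X %*% beta
  centroids <- apply(scores, 2, function(s) tapply(s, labels, mean))
  centroids <- matrix(centroids, nrow = K,
                      dimnames = list(levels(labels), NULL))
  new("SparseDiscriminantModel", beta = beta, theta = theta,
      centroids = centroids, classes = levels(labels),
      featureNames = fm$featureNames, center = fm$center, scale = fm$scale,
      hyperparams = list(lambda = lambda, budget = budget),
      converged = converged, iterations = iterations)
}

#' Project features onto the discriminant directions
#'
#' Standardizes raw features with the model's stored parameters (restricted
#' to the retained feature columns) and returns the LDD scores X beta.
#'
#' @param model a [SparseDiscriminantModel-class].
#' @param x subjects x regions matrix of raw nodal strengths; columns must
#'   cover the model's \code{featureNames}.
#' @return subjects x Q score matrix.
#' @export
projectScores <- function(model, x) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%03d", seq_len(ncol(x)))
  if (!all(model@featureNames %in% colnames(x)))
    stop("feature columns do not match the fitted model")
  xs <- scale(x[, model@featureNames, drop = FALSE], center = model@center,
              scale = model@scale)
  xs %*% model@beta
}

#' Nearest-centroid classification in LDD space
#'
#' Euclidean nearest centroid; ties break deterministically toward the first
#' class in the stored class order.
#'
#' @param scores subjects x Q score matrix.
#' @param centroids K x Q centroid matrix with class rownames, or a fitted
#'   [SparseDiscriminantModel-class].
#' @return factor of predicted class labels.
#' @export
nearestCentroidClassify <- function(scores, centroids) {
  if (methods::is(centroids, "SparseDiscriminantModel"))
    centroids <- centroids@centroids
  scores <- as.matrix(scores)
  d2 <- vapply(seq_len(nrow(centroids)), function(k)
    rowSums(sweep(scores, 2, centroids[k, ], "-")^2),
    numeric(nrow(scores)))
  d2 <- matrix(d2, nrow = nrow(scores))
  idx <- apply(d2, 1, which.min)
  factor(rownames(centroids)[idx], levels = rownames(centroids))
}

#' Baseline classification errors
#'
#' Chance level 1 - 1/K and the leave-one-out error of the majority-class
#' predictor (the majority is recomputed with each subject held out; ties
#' break toward the first class in level order).
#'
#' @param labels factor/character of class labels.
#' @param K number of classes (default: number of observed levels).
#' @return a list with \code{chance} and \code{naive}.
#' @examples
#' baselineErrors(rep(c("II", "IIIa", "IIIb", "IIIc"),
#'                    c(25, 17, 17, 12)))
#' @export
baselineErrors <- function(labels, K = NULL) {
  labels <- if (is.factor(labels)) droplevels(labels) else
    factor(labels, levels = unique(labels))
  if (is.null(K)) K <- nlevels(labels)
  n <- length(labels)
  pred <- vapply(seq_len(n), function(i) {
    tab <- table(labels[-i])
    names(tab)[which.max(tab)]
  }, "")
  list(chance = 1 - 1 / K, naive = mean(pred != as.character(labels)))
}

#' Inter-class distances in LDD space
#'
#' @param centroids K x Q centroid matrix (or a fitted model).
#' @return a list with \code{distance_matrix} (K x K Euclidean, symmetric,
#'   zero diagonal) and \code{avg_distance} (per-class mean over the other
#'   K - 1 classes).
#' @export
interclassDistances <- function(centroids) {
  if (methods::is(centroids, "SparseDiscriminantModel"))
    centroids <- centroids@centroids
  dm <- as.matrix(stats::dist(centroids))
  avg <- rowSums(dm) / (nrow(dm) - 1)
  list(distance_matrix = dm, avg_distance = avg)
}

#' Leave-one-out evaluation of the sparse discriminant model
#'
#' For every held-out subject the features are re-standardized and the model
#' re-fitted on the remaining subjects (no leakage), the held-out subject is
#' projected and classified by nearest centroid, and the misclassified
#' fraction is accumulated. The confusion matrix is row-normalized to
#' percentages of true class size. Centroid distances are reported from the
#' full-data model.
#'
#' @param x subjects x regions matrix of raw nodal strengths.
#' @param labels per-subject class labels (every class needs >= 2 subjects).
#' @param lambda,budget hyperparameters passed to [fitSparseDiscriminant()].
#' @return a [DiscriminantEvaluation-class] object.
#' @export
loocvEvaluate <- function(x, labels, lambda = 1e-3, budget = 15) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%03d", seq_len(ncol(x)))
  labels <- if (is.factor(labels)) droplevels(labels) else
    factor(labels, levels = unique(labels))
  n <- nrow(x)
  stopifnot(n == length(labels))
  pred <- character(n)
  for (i in seq_len(n)) {
    fit <- tryCatch(
      suppressWarnings(fitSparseDiscriminant(x[-i, , drop = FALSE],
                                             labels[-i], lambda = lambda,
                                             budget = budget)),
      error = function(e) stop(sprintf("LOOCV fold %d failed: %s", i,
                                       conditionMessage(e))))
    sc <- projectScores(fit, x[i, , drop = FALSE])
    pred[i] <- as.character(nearestCentroidClassify(sc, fit))
  }
  pred <- factor(pred, levels = levels(labels))
  K <- nlevels(labels)
  conf <- table(true = labels, predicted = pred)
  confPct <- sweep(unclass(conf), 1, rowSums(conf), "/") * 100
  base <- baselineErrors(labels, K)
  full <- suppressWarnings(fitSparseDiscriminant(x, labels, lambda = lambda,
                                                 budget = budget))
  dd <- interclassDistances(full)
  new("DiscriminantEvaluation",
      loocvError = mean(pred != labels), confusion = confPct,
      distanceMatrix = dd$distance_matrix, avgDistance = dd$avg_distance,
      baselineChance = base$chance, baselineNaive = base$naive,
      predicted = pred)
}

#' Clinical correlations of discriminant scores
#'
#' Pearson correlation of each LDD score with duration of illness and
#' processing speed (patients only; missing values handled pairwise).
#'
#' @param scores subjects x Q LDD score matrix (patients).
#' @param subjects patient rows of the subject table, aligned with
#'   \code{scores}.
#' @param vars clinical columns to correlate (default \code{doi},
#'   \code{processing_speed}).
#' @return tidy \code{data.frame} with \code{ldd}, \code{variable}, \code{r},
#'   \code{p}, \code{n}.
#' @export
lddClinicalCorrelations <- function(scores, subjects,
                                    vars = c("doi", "processing_speed")) {
  scores <- as.matrix(scores)
  stopifnot(nrow(scores) == nrow(subjects))
  vars <- intersect(vars, names(subjects))
  rows <- list()
  for (q in seq_len(ncol(scores))) for (v in vars) {
    pc <- pearsonCorrelation(scores[, q], subjects[[v]])
    rows[[length(rows) + 1L]] <- data.frame(
      ldd = q, variable = v, r = pc$r, p = pc$p, n = pc$n,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
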