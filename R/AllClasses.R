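#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))
setClassUnion("arrayOrNULL", c("array", "NULL"))

#' Single-subject structural connectome
#'
#' A weighted, undirected whole-brain network. Edge weights are streamline
#' counts between atlas regions; optional per-edge scalar maps carry
#' tract-average generalized fractional anisotropy (gFA, unitless in [0, 1])
#' and apparent diffusion coefficient (ADC, mm^2/s). The scalar maps are
#' defined exactly on the support of the weight matrix and are \code{NA}
#' elsewhere.
#'
#' @slot weights square symmetric nonnegative numeric matrix with zero
#'   diagonal (streamline counts).
#' @slot gfa optional square matrix of tract-average gFA, \code{NA} where
#'   \code{weights == 0}.
#' @slot adc optional square matrix of tract-average ADC (mm^2/s), same
#'   support convention as \code{gfa}.
#' @slot subjectId length-one character identifier.
#'
#' @seealso [Connectome()] for the validating constructor,
#'   [networkMeasures()], [applyMask()].
#' @exportClass Connectome
setClass("Connectome",
  representation(
    weights = "matrix",
    gfa = "matrixOrNULL",
    adc = "matrixOrNULL",
    subjectId = "character"
  )
)

.validScalarMap <- function(map, weights, name, lo = -Inf, hi = Inf) {
  msg <- character()
  if (!is.null(map)) {
    if (!identical(dim(map), dim(weights)))
      msg <- c(msg, sprintf("'%s' dimensions differ from 'weights'", name))
    else {
      sup <- weights > 0
      if (any(is.na(map[sup])))
        msg <- c(msg, sprintf("'%s' undefined on present edges", name))
      if (any(!is.na(map[!sup])))
        msg <- c(msg, sprintf("'%s' defined outside the weight support", name))
      vals <- map[sup]
      if (length(vals) && (any(vals < lo) || any(vals > hi)))
        msg <- c(msg, sprintf("'%s' values outside [%g, %g]", name, lo, hi))
      if (!isTRUE(all.equal(map[sup], t(map)[sup], check.attributes = FALSE)))
        msg <- c(msg, sprintf("'%s' is not symmetric", name))
    }
  }
  msg
}

setValidity("Connectome", function(object) {
  w <- object@weights
  msg <- character()
  if (nrow(w) != ncol(w)) msg <- c(msg, "'weights' must be square")
  if (any(!is.finite(w))) msg <- c(msg, "'weights' must be finite")
  else {
    if (any(w < 0)) msg <- c(msg, "'weights' must be nonnegative")
    if (any(diag(w) != 0)) msg <- c(msg, "'weights' diagonal must be zero")
    if (!isSymmetric(unname(w))) msg <- c(msg, "'weights' must be symmetric")
  }
  msg <- c(msg, .validScalarMap(object@gfa, w, "gfa", 0, 1))
  msg <- c(msg, .validScalarMap(object@adc, w, "adc", 0, Inf))
  if (length(object@subjectId) != 1L)
    msg <- c(msg, "'subjectId' must be length one")
  if (length(msg)) msg else TRUE
})

#' Cohort of aligned connectomes
#'
#' Stacks the per-subject weight (and optional gFA/ADC) matrices of a cohort
#' into region x region x subject arrays sharing one atlas. Subject order is
#' aligned with the clinical metadata table used downstream.
#'
#' @slot atlas a region atlas \code{data.frame}; see [regionAtlas()].
#' @slot weights numeric array, regions x regions x subjects.
#' @slot gfa,adc optional arrays with the same dimensions as \code{weights}.
#' @slot subjectIds character vector of unique subject identifiers, third
#'   array dimension.
#'
#' @seealso [CohortConnectomes()], [consistencyMask()], [nodalStrength()].
#' @exportClass CohortConnectomes
setClass("CohortConnectomes",
  representation(
    atlas = "data.frame",
    weights = "array",
    gfa = "arrayOrNULL",
    adc = "arrayOrNULL",
    subjectIds = "character"
  )
)

setValidity("CohortConnectomes", function(object) {
  msg <- character()
  d <- dim(object@weights)
  if (length(d) != 3L) msg <- c(msg, "'weights' must be a 3-D array")
  else {
    if (d[1] != d[2]) msg <- c(msg, "connectome matrices must be square")
    if (d[1] != nrow(object@atlas))
      msg <- c(msg, "matrix dimension does not match the atlas")
    if (d[3] != length(object@subjectIds))
      msg <- c(msg, "number of subjects does not match 'subjectIds'")
    for (s in c("gfa", "adc")) {
      a <- slot(object, s)
      if (!is.null(a) && !identical(dim(a), d))
        msg <- c(msg, sprintf("'%s' dimensions differ from 'weights'", s))
    }
  }
  if (anyDuplicated(object@subjectIds))
    msg <- c(msg, "subject ids must be unique")
  am <- .checkAtlas(object@atlas)
  if (!isTRUE(am)) msg <- c(msg, am)
  if (length(msg)) msg else TRUE
})

#' Cohort-consistency edge mask
#'
#' Records, for every region pair, the fraction of subjects in which the
#' connection is present (weight > 0) and whether the edge is retained at the
#' chosen consistency threshold. Edges present in fewer than
#' \code{threshold} of the subjects are discarded; ties at exactly the
#' threshold are retained.
#'
#' @slot retained square logical matrix with \code{FALSE} diagonal.
#' @slot threshold consistency fraction in (0, 1].
#' @slot presenceFreq square numeric matrix of presence fractions in [0, 1].
#'
#' @seealso [consistencyMask()], [applyMask()].
#' @exportClass ConsistencyMask
setClass("ConsistencyMask",
  representation(
    retained = "matrix",
    threshold = "numeric",
    presenceFreq = "matrix"
  )
)

setValidity("ConsistencyMask", function(object) {
  msg <- character()
  r <- object@retained
  f <- object@presenceFreq
  if (!is.logical(r)) msg <- c(msg, "'retained' must be logical")
  if (!identical(dim(r), dim(f)))
    msg <- c(msg, "'retained' and 'presenceFreq' dimensions differ")
  else {
    if (any(diag(r))) msg <- c(msg, "'retained' diagonal must be FALSE")
    if (!isSymmetric(unname(r * 1))) msg <- c(msg, "'retained' must be symmetric")
    off <- row(f) != col(f)
    ok <- (f >= object@threshold) & off
    if (!identical(unname(r & off), unname(ok)))
      msg <- c(msg, "'retained' must equal presenceFreq >= threshold off-diagonal")
  }
  if (length(object@threshold) != 1L || object@threshold <= 0 ||
      object@threshold > 1)
    msg <- c(msg, "'threshold' must be a single value in (0, 1]")
  if (any(f < 0 | f > 1)) msg <- c(msg, "'presenceFreq' must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Nodal trend-scan result
#'
#' Per-region Jonckheere-Terpstra statistics and one-sided p-values for an
#' ordered decrease of nodal strength across clinical stages, together with
#' the vulnerable node set selected at an uncorrected alpha and the subset
#' surviving Benjamini-Hochberg FDR control.
#'
#' @slot table per-node \code{data.frame} with columns \code{node},
#'   \code{label}, \code{statistic}, \code{p}, \code{vulnerable},
#'   \code{fdr_significant}.
#' @slot alpha uncorrected selection threshold.
#' @slot fdrQ FDR level for the corrected flags.
#' @slot vulnerable integer region indices with \code{p < alpha}.
#' @slot fdrSignificant integer subset of \code{vulnerable} surviving FDR.
#'
#' @seealso [nodalJtScan()], [subnetworkStrengths()].
#' @exportClass TrendScanResult
setClass("TrendScanResult",
  representation(
    table = "data.frame",
    alpha = "numeric",
    fdrQ = "numeric",
    vulnerable = "integer",
    fdrSignificant = "integer"
  )
)

setValidity("TrendScanResult", function(object) {
  msg <- character()
  if (!all(object@fdrSignificant %in% object@vulnerable))
    msg <- c(msg, "FDR-significant nodes must be a subset of the vulnerable set")
  tab <- object@table
  need <- c("node", "label", "statistic", "p", "vulnerable", "fdr_significant")
  if (!all(need %in% names(tab)))
    msg <- c(msg, "scan table is missing required columns")
  else if (!setequal(tab$node[tab$vulnerable], object@vulnerable))
    msg <- c(msg, "'vulnerable' slot disagrees with the table flags")
  if (length(msg)) msg else TRUE
})

#' Sparse discriminant model from penalized optimal scoring
#'
#' Q = K - 1 sparse linear discriminant directions (LDDs) over standardized
#' nodal-strength features, fitted by alternating penalized optimal scoring:
#' an elastic-net regression step for the direction and a class-score update
#' kept orthonormal in the class-proportion inner product.
#'
#' @slot beta regions x Q matrix of sparse discriminant loadings.
#' @slot theta K x Q optimal-score matrix (columns orthonormal under the
#'   class-proportion inner product).
#' @slot centroids K x Q class centroids in LDD score space.
#' @slot classes ordered class labels (rows of \code{theta}/\code{centroids}).
#' @slot featureNames names of the retained (non-constant) feature columns.
#' @slot center,scale standardization parameters of the training features.
#' @slot hyperparams list with \code{lambda} (ridge) and \code{budget}
#'   (maximum nonzero loadings per LDD).
#' @slot converged logical per LDD; \code{iterations} integer per LDD.
#' @slot iterations integer vector of alternating iterations per LDD.
#'
#' @seealso [fitSparseDiscriminant()], [projectScores()], [loocvEvaluate()].
#' @exportClass SparseDiscriminantModel
setClass("SparseDiscriminantModel",
  representation(
    beta = "matrix",
    theta = "matrix",
    centroids = "matrix",
    classes = "character",
    featureNames = "character",
    center = "numeric",
    scale = "numeric",
    hyperparams = "list",
    converged = "logical",
    iterations = "integer"
  )
)

setValidity("SparseDiscriminantModel", function(object) {
  msg <- character()
  K <- length(object@classes)
  Q <- ncol(object@beta)
  if (Q != K - 1L) msg <- c(msg, "number of LDDs must equal K - 1")
  if (!identical(dim(object@theta), c(K, Q)))
    msg <- c(msg, "'theta' must be K x Q")
  if (!identical(dim(object@centroids), c(K, Q)))
    msg <- c(msg, "'centroids' must be K x Q")
  m <- object@hyperparams$budget
  if (!is.null(m) && any(colSums(object@beta != 0) > m))
    msg <- c(msg, "a discriminant direction exceeds the sparsity budget")
  if (length(msg)) msg else TRUE
})

#' Leave-one-out evaluation of a sparse discriminant model
#'
#' @slot loocvError misclassified fraction under leave-one-out
#'   cross-validation with nearest-centroid classification in LDD space.
#' @slot confusion K x K matrix of percentages; rows are true classes and
#'   each row sums to 100 (share of the true class size).
#' @slot distanceMatrix K x K Euclidean distances between class centroids of
#'   the full-data model.
#' @slot avgDistance per-class mean distance to the other classes.
#' @slot baselineChance 1 - 1/K.
#' @slot baselineNaive LOOCV error of the majority-class predictor.
#' @slot predicted factor of LOOCV-predicted labels, one per subject.
#'
#' @seealso [loocvEvaluate()], [baselineErrors()].
#' @exportClass DiscriminantEvaluation
setClass("DiscriminantEvaluation",
  representation(
    loocvError = "numeric",
    confusion = "matrix",
    distanceMatrix = "matrix",
    avgDistance = "numeric",
    baselineChance = "numeric",
    baselineNaive = "numeric",
    predicted = "factor"
  )
)

setValidity("DiscriminantEvaluation", function(object) {
  msg <- character()
  if (object@loocvError < 0 || object@loocvError > 1)
    msg <- c(msg, "'loocvError' must lie in [0, 1]")
  if (any(abs(rowSums(object@confusion) - 100) > 0.5))
    msg <- c(msg, "confusion rows must sum to 100")
  dm <- object@distanceMatrix
  if (!isSymmetric(unname(dm)) || any(diag(dm) != 0))
    msg <- c(msg, "'distanceMatrix' must be symmetric with zero diagonal")
  if (length(msg)) msg else TRUE
})

#' Planted ground truth of a synthetic cohort
#'
#' @slot vulnerableNodes integer indices of the planted vulnerable regions.
#' @slot stageProfiles named list mapping stage classes to their affected
#'   node subsets (IIIa distinct; IIIb and IIIc shared).
#' @slot cognitionRho planted within-group correlation between vulnerable
#'   subnetwork strength and the processing-speed score.
#' @slot config the generating configuration, echoed.
#'
#' @seealso [generateCohort()], [truthReport()].
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
  representation(
    vulnerableNodes = "integer",
    stageProfiles = "list",
    cognitionRho = "numeric",
    config = "list"
  )
)
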