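#' Construct a single-subject connectome
#'
#' @param weights square symmetric nonnegative matrix of streamline counts,
#'   zero diagonal.
#' @param gfa,adc optional per-edge scalar matrices (tract-average gFA and
#'   ADC). Values off the weight support are set to \code{NA}; present edges
#'   must carry finite values.
#' @param subjectId subject identifier.
#' @return a validated [Connectome-class] object.
#' @examples
#' w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 2; w[1, 3] <- w[3, 1] <- 3
#' con <- Connectome(w, subjectId = "s1")
#' totalStrength(con)
#' @export
Connectome <- function(weights, gfa = NULL, adc = NULL, subjectId = "subject") {
  weights <- as.matrix(weights)
  storage.mode(weights) <- "double"
  fix <- function(map) {
    if (is.null(map)) return(NULL)
    map <- as.matrix(map)
    storage.mode(map) <- "double"
    map[weights == 0] <- NA_real_
    map
  }
  new("Connectome", weights = weights, gfa = fix(gfa), adc = fix(adc),
      subjectId = as.character(subjectId))
}

#' Construct a cohort of connectomes
#'
#' @param connectomes a list of [Connectome-class] objects or of square
#'   weight matrices, all with the same dimension; or a 3-D array
#'   (regions x regions x subjects).
#' @param atlas region atlas \code{data.frame} (default [regionAtlas()] when
#'   the dimension is 82, otherwise a minimal generated atlas).
#' @param subjectIds subject identifiers; taken from the connectomes when
#'   omitted.
#' @param gfa,adc optional lists of scalar matrices or 3-D arrays parallel to
#'   \code{connectomes} (ignored when \code{connectomes} holds
#'   \code{Connectome} objects, which carry their own maps).
#' @return a validated [CohortConnectomes-class] object.
#' @export
CohortConnectomes <- function(connectomes, atlas = NULL, subjectIds = NULL,
                              gfa = NULL, adc = NULL) {
  if (is.array(connectomes) && length(dim(connectomes)) == 3L) {
    W <- connectomes
  } else if (is.list(connectomes) && length(connectomes) > 0) {
    if (methods::is(connectomes[[1]], "Connectome")) {
      if (is.null(subjectIds))
        subjectIds <- vapply(connectomes, function(x) x@subjectId, "")
      gfa <- if (!is.null(connectomes[[1]]@gfa))
        lapply(connectomes, function(x) x@gfa)
      adc <- if (!is.null(connectomes[[1]]@adc))
        lapply(connectomes, function(x) x@adc)
      connectomes <- lapply(connectomes, function(x) x@weights)
    }
    dims <- vapply(connectomes, function(m) dim(as.matrix(m)), integer(2))
    if (length(unique(as.vector(dims))) != 1L)
      stop("connectome matrices have mismatching dimensions")
    W <- simplify2array(lapply(connectomes, as.matrix))
  } else stop("empty cohort: no connectomes supplied")
  stack <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.list(x)) x <- simplify2array(lapply(x, as.matrix))
    storage.mode(x) <- "double"
    x
  }
  storage.mode(W) <- "double"
  n <- dim(W)[3]
  if (is.null(subjectIds)) subjectIds <- sprintf("sub-%03d", seq_len(n))
  if (is.null(atlas)) {
    atlas <- if (dim(W)[1] == 82L) regionAtlas() else
      data.frame(region_id = seq_len(dim(W)[1]),
                 label = sprintf("region-%02d", seq_len(dim(W)[1])),
                 hemisphere = "midline", tissue_class = "cortical",
                 stringsAsFactors = FALSE)
  }
  new("CohortConnectomes", atlas = atlas, weights = W, gfa = stack(gfa),
      adc = stack(adc), subjectIds = as.character(subjectIds))
}

#' @rdname cohort-accessors
#' @export
setGeneric("nSubjects", function(object) standardGeneric("nSubjects"))

#' @rdname cohort-accessors
#' @export
setGeneric("nRegions", function(object) standardGeneric("nRegions"))

#' @rdname cohort-accessors
#' @export
setGeneric("subjectIds", function(object) standardGeneric("subjectIds"))

#' @rdname cohort-accessors
#' @export
setGeneric("atlas", function(object) standardGeneric("atlas"))

#' Cohort accessors
#'
#' @param object a [CohortConnectomes-class] object.
#' @return \code{nSubjects}/\code{nRegions} return integers;
#'   \code{subjectIds} a character vector; \code{atlas} the region table;
#'   \code{getConnectome} a single [Connectome-class].
#' @name cohort-accessors
#' @aliases nSubjects,CohortConnectomes-method
#' @export
setMethod("nSubjects", "CohortConnectomes", function(object)
  dim(object@weights)[3])

#' @rdname cohort-accessors
#' @export
setMethod("nRegions", "CohortConnectomes", function(object)
  dim(object@weights)[1])

#' @rdname cohort-accessors
#' @export
setMethod("subjectIds", "CohortConnectomes", function(object)
  object@subjectIds)

#' @rdname cohort-accessors
#' @export
setMethod("atlas", "CohortConnectomes", function(object) object@atlas)

#' @rdname cohort-accessors
#' @param i subject index or id.
#' @export
getConnectome <- function(object, i) {
  stopifnot(methods::is(object, "CohortConnectomes"))
  if (is.character(i)) i <- match(i, object@subjectIds)
  Connectome(object@weights[, , i],
             gfa = if (!is.null(object@gfa)) object@gfa[, , i],
             adc = if (!is.null(object@adc)) object@adc[, , i],
             subjectId = object@subjectIds[i])
}

setMethod("show", "Connectome", function(object) {
  w <- object@weights
  cat(sprintf(
    "Connectome '%s': %d regions, %d edges, total strength %g\n",
    object@subjectId, nrow(w), sum(w[upper.tri(w)] > 0),
    sum(w[upper.tri(w)])))
  cat(sprintf("  gFA map: %s; ADC map: %s\n",
              if (is.null(object@gfa)) "absent" else "present",
              if (is.null(object@adc)) "absent" else "present"))
})

setMethod("show", "CohortConnectomes", function(object) {
  cat(sprintf("CohortConnectomes: %d subjects x %d regions\n",
              nSubjects(object), nRegions(object)))
  cat(sprintf("  atlas: %d cortical, %d subcortical regions\n",
              sum(object@atlas$tissue_class == "cortical"),
              sum(object@atlas$tissue_class == "subcortical")))
  cat(sprintf("  edge scalar maps: %s\n",
              paste(c("gFA", "ADC")[!c(is.null(object@gfa),
                                       is.null(object@adc))],
                    collapse = ", ")))
})

setMethod("show", "ConsistencyMask", function(object) {
  n <- nrow(object@retained)
  cat(sprintf(
    "ConsistencyMask: %d regions, threshold %.2f, %d/%d edges retained\n",
    n, object@threshold, sum(object@retained[upper.tri(object@retained)]),
    n * (n - 1) / 2))
})

setMethod("show", "TrendScanResult", function(object) {
  cat(sprintf(
    "TrendScanResult: %d regions scanned, %d vulnerable at p < %g, %d FDR-significant at q = %g\n",
    nrow(object@table), length(object@vulnerable), object@alpha,
    length(object@fdrSignificant), object@fdrQ))
})

setMethod("show", "SparseDiscriminantModel", function(object) {
  cat(sprintf(
    "SparseDiscriminantModel: %d classes (%s), %d LDDs over %d features\n",
    length(object@classes), paste(object@classes, collapse = ", "),
    ncol(object@beta), nrow(object@beta)))
  cat(sprintf("  nonzero loadings per LDD: %s (budget %d, ridge %g)\n",
              paste(colSums(object@beta != 0), collapse = ", "),
              object@hyperparams$budget, object@hyperparams$lambda))
})

setMethod("show", "DiscriminantEvaluation", function(object) {
  cat(sprintf(
    "DiscriminantEvaluation: LOOCV error %.3f (chance %.3f, naive %.3f)\n",
    object@loocvError, object@baselineChance, object@baselineNaive))
})
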