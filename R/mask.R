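#' Cohort-consistency edge mask
#'
#' Computes, for every region pair, the fraction of subjects in which the
#' connection is present (streamline count > 0) and retains edges present in
#' at least \code{threshold} of the subjects. With the default threshold of
#' 0.5, connections present in less than half of the cohort are discarded;
#' an edge present in exactly half is retained.
#'
#' @param cohort a [CohortConnectomes-class] object.
#' @param threshold consistency fraction in (0, 1]; default 0.5.
#' @return a [ConsistencyMask-class] object.
#' @examples
#' cohort <- generateCohort(syntheticConfig(
#'   groupSizes = c(HC = 4, II = 2, IIIa = 2, IIIb = 2, IIIc = 2),
#'   nRegions = 10, seed = 1))$cohort
#' mask <- consistencyMask(cohort)
#' mask
#' @export
consistencyMask <- function(cohort, threshold = 0.5) {
  stopifnot(methods::is(cohort, "CohortConnectomes"))
  if (nSubjects(cohort) < 1L) stop("empty cohort")
  if (length(threshold) != 1L || threshold <= 0 || threshold > 1)
    stop("'threshold' must be a single value in (0, 1]")
  freq <- apply(cohort@weights > 0, c(1, 2), mean)
  retained <- freq >= threshold
  diag(retained) <- FALSE
  new("ConsistencyMask", retained = retained, threshold = threshold,
      presenceFreq = freq)
}

#' Apply a consistency mask
#'
#' Zeroes the weights (and blanks the gFA/ADC values) of edges not retained
#' by the mask. Symmetry and the scalar-map support convention are preserved;
#' applying the same mask twice is a no-op.
#'
#' @param x a [Connectome-class] or [CohortConnectomes-class] object.
#' @param mask a [ConsistencyMask-class] with matching dimension.
#' @return an object of the same class as \code{x}.
#' @export
setGeneric("applyMask", function(x, mask) standardGeneric("applyMask"))

#' @rdname applyMask
#' @export
setMethod("applyMask", "Connectome", function(x, mask) {
  stopifnot(methods::is(mask, "ConsistencyMask"))
  if (!identical(dim(x@weights), dim(mask@retained)))
    stop("mask dimension does not match the connectome")
  w <- x@weights
  w[!mask@retained] <- 0
  Connectome(w, gfa = x@gfa, adc = x@adc, subjectId = x@subjectId)
})

#' @rdname applyMask
#' @export
setMethod("applyMask", "CohortConnectomes", function(x, mask) {
  stopifnot(methods::is(mask, "ConsistencyMask"))
  if (!identical(dim(x@weights)[1:2], dim(mask@retained)))
    stop("mask dimension does not match the cohort")
  drop3 <- function(a, keepNA) {
    if (is.null(a)) return(NULL)
    a[] <- apply(a, 3, function(m) {
      m[!mask@retained] <- if (keepNA) NA_real_ else 0
      m
    })
    a
  }
  W <- drop3(x@weights, keepNA = FALSE)
  g <- drop3(x@gfa, keepNA = TRUE)
  d <- drop3(x@adc, keepNA = TRUE)
  if (!is.null(g)) g[W == 0] <- NA_real_
  if (!is.null(d)) d[W == 0] <- NA_real_
  methods::initialize(x, weights = W, gfa = g, adc = d)
})
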