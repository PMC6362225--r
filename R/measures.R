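#' Nodal strength
#'
#' Weighted degree of each region: the sum of a node's streamline counts.
#'
#' @param x a [Connectome-class] (returns a vector) or
#'   [CohortConnectomes-class] (returns a subjects x regions matrix).
#' @return numeric vector or matrix of nodal strengths.
#' @export
setGeneric("nodalStrength", function(x) standardGeneric("nodalStrength"))

#' @rdname nodalStrength
#' @export
setMethod("nodalStrength", "Connectome", function(x) rowSums(x@weights))

#' @rdname nodalStrength
#' @export
setMethod("nodalStrength", "CohortConnectomes", function(x) {
  s <- t(apply(x@weights, 3, rowSums))
  dimnames(s) <- list(x@subjectIds, x@atlas$label)
  s
})

#' Total network strength
#'
#' Total streamline count in the network, i.e. the sum of weights over
#' unordered region pairs. Equals half the sum of nodal strengths.
#'
#' @param x a [Connectome-class] object.
#' @return a scalar.
#' @export
totalStrength <- function(x) {
  stopifnot(methods::is(x, "Connectome"))
  sum(x@weights[upper.tri(x@weights)])
}

#' Global efficiency of a weighted network
#'
#' Edges are assigned lengths 1/w; the efficiency is the mean over ordered
#' node pairs of the inverse shortest path length, with unreachable pairs
#' contributing zero. A complete unit-weight graph has efficiency 1.
#'
#' @param x a [Connectome-class] object.
#' @return a scalar in [0, Inf).
#' @export
globalEfficiency <- function(x) {
  stopifnot(methods::is(x, "Connectome"))
  w <- x@weights
  n <- nrow(w)
  if (n < 2L) return(0)
  len <- w
  len[w > 0] <- 1 / w[w > 0]
  g <- igraph::graph_from_adjacency_matrix(len, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, algorithm = "dijkstra")
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Weighted clustering coefficient (Onnela form)
#'
#' Per-node geometric-mean triangle intensity on weights normalized by the
#' network-wide maximum: C_i = sum over triangles at i of the cube-rooted
#' products of the three normalized weights, divided by k_i (k_i - 1) where
#' k_i is the binary degree. Nodes with degree < 2 get 0. A triangle of equal
#' weights that are the network maximum scores 1.
#'
#' @param x a [Connectome-class] object.
#' @return numeric vector, one coefficient per region.
#' @export
weightedClustering <- function(x) {
  stopifnot(methods::is(x, "Connectome"))
  w <- x@weights
  if (max(w) == 0) return(rep(0, nrow(w)))
  wh <- (w / max(w))^(1 / 3)
  t3 <- diag(wh %*% wh %*% wh)
  k <- rowSums(w > 0)
  denom <- k * (k - 1)
  cc <- ifelse(denom > 0, t3 / denom, 0)
  unname(cc)
}

#' Global and nodal network measures for one connectome
#'
#' Computes the summary measures of a (typically masked) connectome: total
#' strength, whole-brain tract-average gFA and ADC (unweighted means over
#' present edges by default; streamline-count weighted as an option), global
#' efficiency and mean Onnela clustering. When no edges survive, the
#' tract-average scalars are returned as \code{NA} rather than zero.
#'
#' @param x a [Connectome-class] object.
#' @param edgeAverage \code{"plain"} (default, unweighted mean over present
#'   edges) or \code{"count_weighted"} (weights the per-edge scalar by the
#'   streamline count).
#' @return a list with \code{nodal_strength}, \code{total_strength},
#'   \code{mean_gfa}, \code{mean_adc}, \code{global_efficiency},
#'   \code{mean_clustering}.
#' @export
networkMeasures <- function(x, edgeAverage = c("plain", "count_weighted")) {
  stopifnot(methods::is(x, "Connectome"))
  edgeAverage <- match.arg(edgeAverage)
  w <- x@weights
  up <- upper.tri(w)
  present <- up & w > 0
  avg <- function(map) {
    if (is.null(map) || !any(present)) return(NA_real_)
    v <- map[present]
    if (edgeAverage == "plain") mean(v) else
      sum(v * w[present]) / sum(w[present])
  }
  list(
    nodal_strength = rowSums(w),
    total_strength = sum(w[up]),
    mean_gfa = avg(x@gfa),
    mean_adc = avg(x@adc),
    global_efficiency = globalEfficiency(x),
    mean_clustering = mean(weightedClustering(x))
  )
}

#' Per-subject network measures for a cohort
#'
#' @param cohort a [CohortConnectomes-class] object, usually after
#'   [applyMask()].
#' @param edgeAverage see [networkMeasures()].
#' @return a tidy \code{data.frame}, one row per subject, with columns
#'   \code{subject_id}, \code{total_strength}, \code{mean_gfa},
#'   \code{mean_adc}, \code{global_efficiency}, \code{mean_clustering}.
#' @export
cohortMeasures <- function(cohort, edgeAverage = c("plain", "count_weighted")) {
  stopifnot(methods::is(cohort, "CohortConnectomes"))
  edgeAverage <- match.arg(edgeAverage)
  rows <- lapply(seq_len(nSubjects(cohort)), function(i) {
    m <- networkMeasures(getConnectome(cohort, i), edgeAverage)
    data.frame(subject_id = cohort@subjectIds[i],
               total_strength = m$total_strength, mean_gfa = m$mean_gfa,
               mean_adc = m$mean_adc, global_efficiency = m$global_efficiency,
               mean_clustering = m$mean_clustering, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Hub ranking by cohort-mean nodal strength
#'
#' Ranks regions by their cohort-mean nodal strength on the masked
#' connectomes and flags hubs as regions whose mean strength exceeds the
#' across-region mean by more than \code{sdFactor} standard deviations.
#'
#' @param cohort a [CohortConnectomes-class] object.
#' @param mask optional [ConsistencyMask-class] applied before ranking.
#' @param sdFactor hub threshold in across-region SD units (default 1).
#' @return a \code{data.frame} sorted by rank with columns \code{rank},
#'   \code{node}, \code{label}, \code{mean_strength}, \code{hub}.
#' @export
hubRanking <- function(cohort, mask = NULL, sdFactor = 1) {
  stopifnot(methods::is(cohort, "CohortConnectomes"))
  if (!is.null(mask)) cohort <- applyMask(cohort, mask)
  ms <- colMeans(nodalStrength(cohort))
  thr <- mean(ms) + sdFactor * stats::sd(ms)
  out <- data.frame(
    node = seq_along(ms), label = cohort@atlas$label, mean_strength = ms,
    hub = ms > thr, stringsAsFactors = FALSE, row.names = NULL
  )
  out <- out[order(-out$mean_strength, out$node), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("rank", "node", "label", "mean_strength", "hub")]
}

#' Overlap between two node sets
#'
#' Utility for comparing, e.g., the hub set with a vulnerable node set.
#'
#' @param nodes,reference integer vectors of region indices.
#' @return a list with \code{count} (intersection size) and \code{fraction}
#'   (intersection over the size of \code{nodes}; \code{NA} if empty).
#' @export
nodeSetOverlap <- function(nodes, reference) {
  nodes <- unique(as.integer(nodes))
  reference <- unique(as.integer(reference))
  count <- length(intersect(nodes, reference))
  list(count = count,
       fraction = if (length(nodes)) count / length(nodes) else NA_real_)
}
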