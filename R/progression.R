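.STAGES <- c("HC", "II", "IIIa", "IIIb", "IIIc")
.DEFAULT_COVARIATES <- c("age", "gender", "handedness", "scanner")

#' Collapse stage labels to coarse groups
#'
#' @param group character/factor of stage labels in
#'   \code{HC, II, IIIa, IIIb, IIIc}.
#' @param to \code{"ordered3"} (HC < II < III), \code{"status"} (HC vs EPP)
#'   or \code{"stage4"} (patients' II < IIIa < IIIb < IIIc).
#' @return a factor with ordered levels.
#' @export
collapseStages <- function(group, to = c("ordered3", "status", "stage4")) {
  to <- match.arg(to)
  g <- as.character(group)
  if (!all(g %in% .STAGES))
    stop("stage labels must be among HC, II, IIIa, IIIb, IIIc")
  switch(to,
    ordered3 = factor(ifelse(g == "HC", "HC", ifelse(g == "II", "II", "III")),
                      levels = c("HC", "II", "III")),
    status = factor(ifelse(g == "HC", "HC", "EPP"), levels = c("HC", "EPP")),
    stage4 = factor(g[g != "HC"], levels = c("II", "IIIa", "IIIb", "IIIc"))
  )
}

.checkSubjects <- function(subjects) {
  need <- c("subject_id", "group")
  if (!all(need %in% names(subjects)))
    stop("subject table needs at least subject_id and group columns")
  if (anyDuplicated(subjects$subject_id)) stop("subject ids must be unique")
  if (!all(subjects$group %in% .STAGES))
    stop("stage labels must be among HC, II, IIIa, IIIb, IIIc")
  invisible(subjects)
}

.covariates <- function(subjects, covariates = .DEFAULT_COVARIATES) {
  missing <- setdiff(covariates, names(subjects))
  if (length(missing))
    stop(sprintf("missing covariate columns: %s",
                 paste(missing, collapse = ", ")))
  subjects[, covariates, drop = FALSE]
}

.jtBySample <- function(values, g3, direction, enumerationCap = 1e6) {
  samples <- split(values, g3)
  jonckheereTerpstra(samples, direction = direction,
                     enumerationCap = enumerationCap)
}

#' Ordered-progression analysis of global network measures
#'
#' For each global measure (total strength, tract-average gFA and ADC, global
#' efficiency, mean clustering): residualizes on the covariates, runs the
#' Jonckheere-Terpstra test across the ordered groups HC, II, III with the
#' measure-appropriate direction (decreasing for strength, gFA, efficiency
#' and clustering; increasing for ADC), and adds covariate-adjusted pairwise
#' contrasts (HC vs EPP, HC vs II, HC vs III, II vs III) with Cohen's d.
#'
#' @param measures per-subject measures from [cohortMeasures()].
#' @param subjects subject metadata table aligned with \code{measures}.
#' @param covariates covariate column names (default age, gender, handedness,
#'   scanner).
#' @return a tidy \code{data.frame} with columns \code{measure},
#'   \code{contrast}, \code{n}, \code{statistic}, \code{p}, \code{d},
#'   \code{direction}.
#' @export
globalProgression <- function(measures, subjects,
                              covariates = .DEFAULT_COVARIATES) {
  .checkSubjects(subjects)
  stopifnot(identical(measures$subject_id, subjects$subject_id))
  g3 <- collapseStages(subjects$group, "ordered3")
  if (any(table(g3) == 0L)) stop("a collapsed stage group is empty")
  status <- collapseStages(subjects$group, "status")
  covs <- .covariates(subjects, covariates)
  dirs <- c(total_strength = "decreasing", mean_gfa = "decreasing",
            mean_adc = "increasing", global_efficiency = "decreasing",
            mean_clustering = "decreasing")
  rows <- list()
  for (m in names(dirs)) {
    if (!m %in% names(measures) || all(is.na(measures[[m]]))) next
    y <- measures[[m]]
    res <- residualize(y, covs)
    jt <- .jtBySample(res, g3, dirs[[m]])
    rows[[length(rows) + 1L]] <- data.frame(
      measure = m, contrast = "HC>II>III(JT)", n = length(res),
      statistic = jt$statistic, p = jt$p_value, d = NA_real_,
      direction = dirs[[m]], stringsAsFactors = FALSE)
    contrasts <- list(
      `HC-EPP` = status, `HC-II` = g3, `HC-III` = g3, `II-III` = g3)
    pairs <- list(c("HC", "EPP"), c("HC", "II"), c("HC", "III"),
                  c("II", "III"))
    for (k in seq_along(pairs)) {
      keep <- contrasts[[k]] %in% pairs[[k]]
      gk <- factor(as.character(contrasts[[k]][keep]), levels = pairs[[k]])
      eff <- ancovaGroupEffect(y[keep], gk, covs[keep, , drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        measure = m, contrast = names(contrasts)[k], n = sum(keep),
        statistic = NA_real_, p = eff$p_value, d = eff$cohens_d,
        direction = NA_character_, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Mass-univariate nodal trend scan
#'
#' Scans every region for an ordered decrease of nodal strength across
#' HC, stage II, stage III with the Jonckheere-Terpstra test. Strengths are
#' residualized on the covariates by default (the trend test has no native
#' covariate adjustment). The vulnerable set collects regions with
#' uncorrected p below \code{alpha}; Benjamini-Hochberg flags at level
#' \code{fdrQ} are reported alongside but do not decide membership.
#'
#' @param cohort a masked [CohortConnectomes-class] (apply the consistency
#'   mask first, or pass \code{mask}).
#' @param subjects subject metadata aligned with the cohort.
#' @param mask optional [ConsistencyMask-class] applied before the scan.
#' @param alpha uncorrected selection threshold in (0, 1), default 0.05.
#' @param fdrQ FDR level for the corrected flags, default 0.05.
#' @param covariates covariate column names; \code{NULL} disables adjustment.
#' @param onResiduals run the trend test on covariate residuals (default) or
#'   raw strengths.
#' @return a [TrendScanResult-class] object.
#' @export
nodalJtScan <- function(cohort, subjects, mask = NULL, alpha = 0.05,
                        fdrQ = 0.05, covariates = .DEFAULT_COVARIATES,
                        onResiduals = TRUE) {
  .checkSubjects(subjects)
  if (length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)")
  if (!is.null(mask)) cohort <- applyMask(cohort, mask)
  stopifnot(nSubjects(cohort) == nrow(subjects))
  S <- nodalStrength(cohort)
  g3 <- collapseStages(subjects$group, "ordered3")
  covs <- if (is.null(covariates)) NULL else .covariates(subjects, covariates)
  stats <- ps <- numeric(ncol(S))
  for (j in seq_len(ncol(S))) {
    y <- S[, j]
    if (onResiduals && !is.null(covs)) y <- residualize(y, covs)
    jt <- .jtBySample(y, g3, "decreasing")
    stats[j] <- jt$statistic
    ps[j] <- jt$p_value
  }
  fdr <- bhFdr(ps, q = fdrQ)
  tab <- data.frame(
    node = seq_len(ncol(S)), label = cohort@atlas$label, statistic = stats,
    p = ps, vulnerable = ps < alpha,
    fdr_significant = fdr$significant, stringsAsFactors = FALSE)
  new("TrendScanResult", table = tab, alpha = alpha, fdrQ = fdrQ,
      vulnerable = which(tab$vulnerable), fdrSignificant = which(fdr$significant))
}

#' Subnetwork strength of a node set
#'
#' Sum of streamline counts over edges with both endpoints inside the node
#' set. The remainder is the total strength minus this sum, so cross edges
#' (one endpoint inside) count toward the remainder.
#'
#' @param x a [Connectome-class] object (masked, typically).
#' @param nodes integer region indices.
#' @return a scalar.
#' @export
subnetworkStrength <- function(x, nodes) {
  stopifnot(methods::is(x, "Connectome"))
  nodes <- unique(as.integer(nodes))
  if (length(nodes) && (min(nodes) < 1L || max(nodes) > nrow(x@weights)))
    stop("unknown node id in the subnetwork set")
  if (length(nodes) < 2L) return(0)
  sub <- x@weights[nodes, nodes, drop = FALSE]
  sum(sub[upper.tri(sub)])
}

#' Per-subject vulnerable and remainder strengths
#'
#' @param cohort a masked [CohortConnectomes-class].
#' @param nodes vulnerable node indices (e.g. from [nodalJtScan()]).
#' @return a \code{data.frame} with \code{subject_id},
#'   \code{vulnerable_strength}, \code{remainder_strength},
#'   \code{total_strength}.
#' @export
subnetworkStrengths <- function(cohort, nodes) {
  stopifnot(methods::is(cohort, "CohortConnectomes"))
  nodes <- unique(as.integer(nodes))
  if (length(nodes) && (min(nodes) < 1L || max(nodes) > nRegions(cohort)))
    stop("unknown node id in the subnetwork set")
  vuln <- vapply(seq_len(nSubjects(cohort)), function(i)
    subnetworkStrength(getConnectome(cohort, i), nodes), 0)
  tot <- vapply(seq_len(nSubjects(cohort)), function(i)
    totalStrength(getConnectome(cohort, i)), 0)
  data.frame(subject_id = cohort@subjectIds, vulnerable_strength = vuln,
             remainder_strength = tot - vuln, total_strength = tot,
             stringsAsFactors = FALSE)
}

#' Coupling between connectivity strength and processing speed
#'
#' Pearson correlations between the processing-speed score and (a) total
#' strength, (b) vulnerable-subnetwork strength, (c) remainder strength,
#' computed separately within healthy controls and within patients.
#'
#' @param subjects subject metadata with \code{processing_speed}.
#' @param strengths output of [subnetworkStrengths()] aligned with
#'   \code{subjects}.
#' @return tidy \code{data.frame} with columns \code{group},
#'   \code{measure}, \code{r}, \code{p}, \code{n}.
#' @export
cognitionCoupling <- function(subjects, strengths) {
  .checkSubjects(subjects)
  stopifnot(identical(subjects$subject_id, strengths$subject_id))
  status <- collapseStages(subjects$group, "status")
  meas <- c(total = "total_strength", vulnerable = "vulnerable_strength",
            remainder = "remainder_strength")
  rows <- list()
  for (grp in levels(status)) {
    keep <- status == grp
    if (sum(keep) < 3L) {
      warning(sprintf("group %s has fewer than 3 subjects; skipped", grp))
      next
    }
    for (m in names(meas)) {
      pc <- pearsonCorrelation(subjects$processing_speed[keep],
                               strengths[[meas[[m]]]][keep])
      rows[[length(rows) + 1L]] <- data.frame(
        group = grp, measure = m, r = pc$r, p = pc$p, n = pc$n,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Clinical correlates of connectivity measures
#'
#' Pearson correlations, in patients only, between each connectivity measure
#' (total strength, vulnerable-subnetwork strength, tract-average gFA and
#' ADC) and the clinical variables: duration of illness, duration of
#' untreated psychosis, PANSS scores, GAF and medication dose. Missing
#' clinical values are handled pairwise; no imputation.
#'
#' @param subjects subject metadata table.
#' @param measures per-subject \code{data.frame} holding columns among
#'   \code{total_strength}, \code{vulnerable_strength}, \code{mean_gfa},
#'   \code{mean_adc}, aligned with \code{subjects}.
#' @param clinicalVars clinical column names to correlate.
#' @return tidy \code{data.frame} with \code{measure}, \code{variable},
#'   \code{r}, \code{p}, \code{n}.
#' @export
clinicalCorrelates <- function(subjects, measures,
                               clinicalVars = c("doi", "dup", "panss_pos",
                                                "panss_neg", "panss_gen",
                                                "panss_total", "gaf", "cpz")) {
  .checkSubjects(subjects)
  stopifnot(identical(subjects$subject_id, measures$subject_id))
  pat <- subjects$group != "HC"
  conn <- intersect(c("total_strength", "vulnerable_strength", "mean_gfa",
                      "mean_adc"), names(measures))
  clinicalVars <- intersect(clinicalVars, names(subjects))
  rows <- list()
  for (m in conn) for (v in clinicalVars) {
    pc <- pearsonCorrelation(measures[[m]][pat], subjects[[v]][pat])
    rows[[length(rows) + 1L]] <- data.frame(
      measure = m, variable = v, r = pc$r, p = pc$p, n = pc$n,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
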