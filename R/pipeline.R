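.RUNCONFIG_KEYS <- c(
  "connectomes", "gfa_dir", "adc_dir", "atlas", "subjects", "out_dir",
  "mask_threshold", "covariates", "alpha", "fdr_q", "jt_enumeration_cap",
  "slda_lambda", "slda_budget", "subset_scanner", "subset_handedness",
  "edge_average", "seed", "log_level"
)

#' Build and validate a pipeline run configuration
#'
#' Accepts a named list (e.g. parsed from YAML or JSON via
#' \code{yaml::read_yaml} / \code{jsonlite::read_json}); unknown keys are
#' rejected. Paths may be omitted when in-memory objects are passed to
#' [runFullAnalysis()] directly.
#'
#' @param ... configuration entries among: \code{connectomes}, \code{gfa_dir},
#'   \code{adc_dir}, \code{atlas}, \code{subjects} (input paths);
#'   \code{out_dir}; \code{mask_threshold} (default 0.5); \code{covariates}
#'   (default age, gender, handedness, scanner); \code{alpha} (0.05);
#'   \code{fdr_q} (0.05); \code{jt_enumeration_cap} (1e6);
#'   \code{slda_lambda} (1e-3); \code{slda_budget} (15);
#'   \code{subset_scanner} (\code{all}/\code{pre}/\code{post});
#'   \code{subset_handedness} (\code{all}/\code{R}); \code{edge_average}
#'   (\code{plain}/\code{count_weighted}); \code{seed}; \code{log_level}.
#' @return a validated list of class \code{runConfig}.
#' @export
runConfig <- function(...) {
  user <- list(...)
  if (length(user) == 1L && is.list(user[[1]]) && is.null(names(user)[1]))
    user <- user[[1]]
  unknown <- setdiff(names(user), .RUNCONFIG_KEYS)
  if (length(unknown))
    stop(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")))
  cfg <- list(
    connectomes = NULL, gfa_dir = NULL, adc_dir = NULL, atlas = NULL,
    subjects = NULL, out_dir = NULL, mask_threshold = 0.5,
    covariates = .DEFAULT_COVARIATES, alpha = 0.05, fdr_q = 0.05,
    jt_enumeration_cap = 1e6, slda_lambda = 1e-3, slda_budget = 15,
    subset_scanner = "all", subset_handedness = "all",
    edge_average = "plain", seed = 1L, log_level = "info")
  cfg[names(user)] <- user
  if (!cfg$subset_scanner %in% c("all", "pre", "post"))
    stop("subset_scanner must be all/pre/post")
  if (!cfg$subset_handedness %in% c("all", "R"))
    stop("subset_handedness must be all/R")
  if (!cfg$edge_average %in% c("plain", "count_weighted"))
    stop("edge_average must be plain/count_weighted")
  if (cfg$mask_threshold <= 0 || cfg$mask_threshold > 1)
    stop("mask_threshold must be in (0, 1]")
  class(cfg) <- "runConfig"
  cfg
}

.applySubset <- function(cohort, subjects, config) {
  keep <- rep(TRUE, nrow(subjects))
  if (config$subset_scanner != "all")
    keep <- keep & subjects$scanner == config$subset_scanner
  if (config$subset_handedness != "all")
    keep <- keep & subjects$handedness == config$subset_handedness
  if (!all(keep)) {
    idx <- which(keep)
    cohort <- methods::initialize(
      cohort, weights = cohort@weights[, , idx, drop = FALSE],
      gfa = if (!is.null(cohort@gfa)) cohort@gfa[, , idx, drop = FALSE],
      adc = if (!is.null(cohort@adc)) cohort@adc[, , idx, drop = FALSE],
      subjectIds = cohort@subjectIds[idx])
    subjects <- subjects[idx, , drop = FALSE]
    rownames(subjects) <- NULL
  }
  list(cohort = cohort, subjects = subjects)
}

#' Cohort comparison table
#'
#' Group comparisons of demographic, cognitive and clinical variables for the
#' contrasts HC vs EPP, II vs III and IIIa vs IIIb vs IIIc: one-way ANOVA for
#' continuous variables, chi-square for categorical ones, with per-group
#' mean (SD) or level-count summaries.
#'
#' @param subjects subject metadata table.
#' @return a \code{data.frame} with one row per variable x contrast, columns
#'   \code{variable}, \code{contrast}, \code{test}, \code{statistic},
#'   \code{p}, \code{summary}.
#' @export
cohortComparisonTable <- function(subjects) {
  .checkSubjects(subjects)
  status <- collapseStages(subjects$group, "status")
  g3 <- collapseStages(subjects$group, "ordered3")
  continuous <- intersect(c("age", "gaf", "processing_speed", "doi", "dup",
                            "panss_pos", "panss_neg", "panss_gen",
                            "panss_total", "cpz"), names(subjects))
  categorical <- intersect(c("gender", "handedness", "scanner"),
                           names(subjects))
  contrasts <- list(
    `HC/EPP` = status,
    `II/III` = factor(ifelse(g3 == "HC", NA, as.character(g3)),
                      levels = c("II", "III")),
    `IIIa/IIIb/IIIc` = factor(ifelse(subjects$group %in%
                                       c("IIIa", "IIIb", "IIIc"),
                                     subjects$group, NA),
                              levels = c("IIIa", "IIIb", "IIIc")))
  rows <- list()
  for (cn in names(contrasts)) {
    grp <- contrasts[[cn]]
    for (v in continuous) {
      ok <- !is.na(grp) & !is.na(subjects[[v]])
      g <- droplevels(grp[ok])
      if (nlevels(g) < 2L || any(table(g) < 2L)) next
      samples <- split(subjects[[v]][ok], g)
      res <- onewayAnova(samples)
      summ <- paste(sprintf("%s: %.1f (%.1f)", names(samples),
                            vapply(samples, mean, 0),
                            vapply(samples, stats::sd, 0)), collapse = "; ")
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, contrast = cn, test = "anova", statistic = res$F,
        p = res$p, summary = summ, stringsAsFactors = FALSE)
    }
    for (v in categorical) {
      ok <- !is.na(grp) & !is.na(subjects[[v]])
      g <- droplevels(grp[ok])
      if (nlevels(g) < 2L) next
      tab <- table(g, subjects[[v]][ok])
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0) || ncol(tab) < 2L)
        next
      res <- chiSquareContingency(unclass(tab))
      summ <- paste(apply(tab, 1, paste, collapse = "/"), collapse = "; ")
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, contrast = cn, test = "chi-square",
        statistic = res$chi2, p = res$p, summary = summ,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Run the full staged-connectome analysis
#'
#' Orchestrates the pipeline end to end: sensitivity subset filter,
#' consistency mask, per-subject network measures, ordered global
#' progression, nodal trend scan, vulnerable/remainder subnetwork strengths
#' and cognition coupling, cohort comparison table, sparse discriminant
#' analysis of patients, discriminant-score and connectivity clinical
#' correlates. All module outputs are written under \code{out_dir} (when
#' given) as TSVs plus a single JSON summary stamped with the config hash and
#' seed. The analysis itself is deterministic given its inputs; the seed is
#' recorded for provenance of upstream simulation.
#'
#' @param config a [runConfig()] object (or list accepted by it).
#' @param cohort,subjects optional in-memory inputs overriding the config
#'   paths.
#' @return invisibly, a list with every stage result and the summary.
#' @export
runFullAnalysis <- function(config = runConfig(), cohort = NULL,
                            subjects = NULL) {
  if (!inherits(config, "runConfig")) config <- runConfig(config)
  t0 <- Sys.time()
  logmsg <- function(stage)
    if (config$log_level != "quiet")
      message(sprintf("[%s] %s (%.1fs)", format(Sys.time(), "%H:%M:%S"),
                      stage, as.numeric(Sys.time() - t0, units = "secs")))
  stage <- "load inputs"
  out <- tryCatch({
    if (is.null(cohort)) {
      atl <- if (!is.null(config$atlas)) readAtlas(config$atlas)
      cohort <- readConnectomeDir(config$connectomes,
                                  gfaDir = config$gfa_dir,
                                  adcDir = config$adc_dir, atlas = atl)
    }
    if (is.null(subjects)) subjects <- readSubjectTable(config$subjects)
    if (!identical(subjectIds(cohort), subjects$subject_id))
      stop("cohort subject ids do not match the metadata table")
    logmsg(stage)

    stage <- "subset filter"
    sub <- .applySubset(cohort, subjects, config)
    cohort <- sub$cohort; subjects <- sub$subjects
    logmsg(stage)

    stage <- "consistency mask"
    mask <- consistencyMask(cohort, config$mask_threshold)
    masked <- applyMask(cohort, mask)
    logmsg(stage)

    stage <- "network measures"
    measures <- cohortMeasures(masked, edgeAverage = config$edge_average)
    logmsg(stage)

    stage <- "global progression"
    progression <- globalProgression(measures, subjects,
                                     covariates = config$covariates)
    logmsg(stage)

    stage <- "nodal trend scan"
    scan <- nodalJtScan(masked, subjects, alpha = config$alpha,
                        fdrQ = config$fdr_q,
                        covariates = config$covariates)
    logmsg(stage)

    stage <- "subnetwork strengths"
    strengths <- subnetworkStrengths(masked, scan@vulnerable)
    coupling <- cognitionCoupling(subjects, strengths)
    logmsg(stage)

    stage <- "cohort comparison table"
    table1 <- cohortComparisonTable(subjects)
    logmsg(stage)

    stage <- "sparse discriminant analysis"
    pat <- subjects$group != "HC"
    S <- nodalStrength(masked)
    lab4 <- collapseStages(subjects$group[pat], "stage4")
    slda <- suppressWarnings(loocvEvaluate(S[pat, , drop = FALSE], lab4,
                                           lambda = config$slda_lambda,
                                           budget = config$slda_budget))
    model <- suppressWarnings(fitSparseDiscriminant(
      S[pat, , drop = FALSE], lab4, lambda = config$slda_lambda,
      budget = config$slda_budget))
    scores <- projectScores(model, S[pat, , drop = FALSE])
    lddCors <- lddClinicalCorrelations(scores, subjects[pat, , drop = FALSE])
    logmsg(stage)

    stage <- "clinical correlates"
    measAug <- cbind(measures,
                     vulnerable_strength = strengths$vulnerable_strength)
    clinCors <- clinicalCorrelates(subjects, measAug)
    logmsg(stage)

    list(mask = mask, measures = measures, progression = progression,
         scan = scan, strengths = strengths, coupling = coupling,
         table1 = table1, slda = slda, model = model, scores = scores,
         ldd_correlations = lddCors, clinical_correlations = clinCors,
         subjects = subjects)
  }, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE))

  cfgHash <- rlang::hash(unclass(config))
  summary <- list(
    config_hash = cfgHash, seed = config$seed,
    n_subjects = nSubjects(cohort), n_regions = nRegions(cohort),
    edges_retained = sum(out$mask@retained[upper.tri(out$mask@retained)]),
    n_vulnerable = length(out$scan@vulnerable),
    n_fdr_significant = length(out$scan@fdrSignificant),
    jt_p_total_strength = out$progression$p[
      out$progression$measure == "total_strength" &
        out$progression$contrast == "HC>II>III(JT)"],
    loocv_error = out$slda@loocvError,
    baseline_chance = out$slda@baselineChance,
    baseline_naive = out$slda@baselineNaive,
    coupling = out$coupling)
  out$summary <- summary

  if (!is.null(config$out_dir)) {
    od <- config$out_dir
    dir.create(od, showWarnings = FALSE, recursive = TRUE)
    writeMask(out$mask, file.path(od, "mask.tsv"))
    writeTsv(out$measures, file.path(od, "measures.tsv"))
    writeTsv(out$progression, file.path(od, "global_progression.tsv"))
    writeTsv(out$scan@table, file.path(od, "nodal_scan.tsv"))
    writeTsv(out$strengths, file.path(od, "subnetwork_strengths.tsv"))
    writeTsv(out$coupling, file.path(od, "cognition_coupling.tsv"))
    writeTsv(out$table1, file.path(od, "cohort_comparisons.tsv"))
    writeTsv(out$ldd_correlations, file.path(od, "ldd_correlations.tsv"))
    writeTsv(out$clinical_correlations,
             file.path(od, "clinical_correlations.tsv"))
    loadings <- data.frame(
      region = rep(rownames(out$model@beta), ncol(out$model@beta)),
      ldd = rep(seq_len(ncol(out$model@beta)), each = nrow(out$model@beta)),
      loading = as.vector(out$model@beta))
    writeTsv(loadings[loadings$loading != 0, ],
             file.path(od, "slda_loadings.tsv"))
    jsonlite::write_json(summary, file.path(od, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}
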