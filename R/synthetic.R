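.TABLE1 <- list(
  age = list(HC = c(26.8, 6.1), II = c(23.5, 4.6), IIIa = c(26.0, 6.3),
             IIIb = c(26.6, 6.1), IIIc = c(30.2, 7.1)),
  male = c(HC = 48 / 76, II = 17 / 25, IIIa = 12 / 17, IIIb = 12 / 17,
           IIIc = 8 / 12),
  right = c(HC = 66 / 76, II = 25 / 25, IIIa = 14 / 17, IIIb = 15 / 17,
            IIIc = 10 / 12),
  pre = c(HC = 63 / 76, II = 15 / 25, IIIa = 10 / 17, IIIb = 12 / 17,
          IIIc = 9 / 12),
  doi = list(II = c(0.8, 1.0), IIIa = c(1.9, 1.6), IIIb = c(4.0, 3.3),
             IIIc = c(7.4, 5.9)),
  dup = list(II = c(107, 233), IIIa = c(320, 545), IIIb = c(585, 963),
             IIIc = c(1282, 1433)),
  gaf = list(HC = c(83, 5), II = c(58, 12), IIIa = c(55, 9), IIIb = c(63, 9),
             IIIc = c(60, 10)),
  panss_pos = list(II = c(13, 5), IIIa = c(14, 4), IIIb = c(12, 4),
                   IIIc = c(13, 5)),
  panss_neg = list(II = c(15, 6), IIIa = c(17, 7), IIIb = c(13, 4),
                   IIIc = c(16, 5)),
  panss_gen = list(II = c(35, 11), IIIa = c(35, 9), IIIb = c(30, 7),
                   IIIc = c(30, 8)),
  cpz = list(II = c(420.5, 218.5), IIIa = c(403.6, 273.1),
             IIIb = c(452.9, 324.2), IIIc = c(388.3, 282.8))
)

#' Synthetic cohort configuration
#'
#' Defaults emulate the reference cohort: 76 controls and 71 patients in
#' stages II/IIIa/IIIb/IIIc (25/17/17/12), 82 regions at ~30% edge density,
#' a planted 22-region vulnerable set whose internal connections attenuate
#' with stage rank (HC 0, II 0.5, stage III 1.0 of \code{deltaMax}),
#' class-specific dysconnectivity profiles inside the vulnerable set (IIIa
#' distinct; IIIb and IIIc shared, so their signatures overlap), diffuse
#' stage shifts on gFA (down) and ADC (up), age/scanner covariate effects on
#' all edges, and a processing-speed score coupled to vulnerable-subnetwork
#' strength. Demographic and clinical marginals are drawn to match the
#' reference cohort table.
#'
#' @param groupSizes named counts for HC, II, IIIa, IIIb, IIIc.
#' @param nRegions number of atlas regions.
#' @param density target edge density of the template in (0, 1).
#' @param vulnerableSetSize number of planted vulnerable regions.
#' @param deltaMax maximal log-attenuation of vulnerable-internal weights.
#' @param stageRanks per-stage multiplier of \code{deltaMax}.
#' @param stageProfiles plant class-specific profiles (logical).
#' @param profileDelta log-attenuation of profile-internal edges.
#' @param gfaDelta,adcDelta per-rank global shift of gFA (subtracted) and ADC
#'   (added, mm^2/s).
#' @param gfaSubjectSd,adcSubjectSd,gfaEdgeSd,adcEdgeSd subject-level offset
#'   and edge-level noise SDs of the scalar maps.
#' @param cognitionBeta processing-speed T-points per SD of vulnerable
#'   strength.
#' @param cognitionNoiseSd residual SD of the processing-speed score.
#' @param speedBase healthy-control mean processing-speed T-score.
#' @param speedShifts per-stage decrement of the speed score.
#' @param ageSlope relative weight change per year of age.
#' @param scannerFactor multiplicative weight factor of post-upgrade scans.
#' @param noiseSd subject-level log-normal SD of edge weights.
#' @param seed integer seed; all randomness is derived from it.
#' @return a validated configuration list of class \code{syntheticConfig}.
#' @export
syntheticConfig <- function(groupSizes = c(HC = 76, II = 25, IIIa = 17,
                                           IIIb = 17, IIIc = 12),
                            nRegions = 82, density = 0.30,
                            vulnerableSetSize = 22, deltaMax = 0.15,
                            stageRanks = c(HC = 0, II = 0.5, IIIa = 1,
                                           IIIb = 1, IIIc = 1),
                            stageProfiles = TRUE, profileDelta = 0.2,
                            gfaDelta = 0.006, adcDelta = 1.5e-5,
                            gfaSubjectSd = 0.012, adcSubjectSd = 3e-5,
                            gfaEdgeSd = 0.02, adcEdgeSd = 5e-5,
                            cognitionBeta = 4, cognitionNoiseSd = 8.25,
                            speedBase = 53,
                            speedShifts = c(HC = 0, II = 9, IIIa = 18,
                                            IIIb = 16, IIIc = 11),
                            ageSlope = -0.003, scannerFactor = 1.03,
                            noiseSd = 0.2, seed = 1) {
  cfg <- list(groupSizes = groupSizes, nRegions = as.integer(nRegions),
              density = density, vulnerableSetSize =
                as.integer(vulnerableSetSize), deltaMax = deltaMax,
              stageRanks = stageRanks, stageProfiles = stageProfiles,
              profileDelta = profileDelta, gfaDelta = gfaDelta,
              adcDelta = adcDelta, gfaSubjectSd = gfaSubjectSd,
              adcSubjectSd = adcSubjectSd, gfaEdgeSd = gfaEdgeSd,
              adcEdgeSd = adcEdgeSd, cognitionBeta = cognitionBeta,
              cognitionNoiseSd = cognitionNoiseSd, speedBase = speedBase,
              speedShifts = speedShifts, ageSlope = ageSlope,
              scannerFactor = scannerFactor, noiseSd = noiseSd,
              seed = as.integer(seed))
  if (!all(.STAGES %in% names(cfg$groupSizes)))
    stop("groupSizes must name HC, II, IIIa, IIIb, IIIc")
  if (any(cfg$groupSizes < 2)) stop("group sizes must be >= 2")
  if (cfg$density <= 0 || cfg$density >= 1) stop("density must be in (0, 1)")
  if (cfg$deltaMax < 0 || cfg$profileDelta < 0)
    stop("effect sizes must be nonnegative")
  if (cfg$vulnerableSetSize > cfg$nRegions)
    stop("vulnerable set larger than the atlas")
  class(cfg) <- "syntheticConfig"
  cfg
}

#' Deterministic edge template for the synthetic cohort
#'
#' Samples region positions in the unit cube, draws edge presence with a
#' distance-decaying probability calibrated to the target density (within
#' 0.02), and assigns base weights (log-normal, location increasing with
#' proximity, rounded to positive integers), base gFA (truncated normal,
#' mean 0.50, SD 0.05) and base ADC (normal, mean 8.0e-4, SD 0.5e-4 mm^2/s).
#'
#' @param config a [syntheticConfig()] list.
#' @param seed integer seed (default the config's).
#' @return a list with square matrices \code{weights}, \code{gfa},
#'   \code{adc} and the \code{positions} used.
#' @export
buildEdgeTemplate <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "syntheticConfig"))
  set.seed(seed)
  n <- config$nRegions
  pos <- matrix(stats::runif(3 * n), n, 3)
  D <- as.matrix(stats::dist(pos))
  Dh <- D / max(D)
  up <- upper.tri(D)
  q <- exp(-Dh[up] / 0.5)
  cc <- config$density / mean(q)
  for (it in 1:25) {
    p <- pmin(cc * q, 0.999)
    gap <- config$density - mean(p)
    if (abs(gap) < 0.002) break
    cc <- cc * config$density / mean(p)
  }
  if (abs(mean(pmin(cc * q, 0.999)) - config$density) > 0.02)
    stop("edge-density target unreachable for this geometry")
  p <- pmin(cc * q, 0.999)
  present <- stats::runif(length(p)) < p
  m <- sum(present)
  wvals <- pmax(round(stats::rlnorm(m, meanlog = log(30) +
                                      1.2 * (1 - Dh[up][present]),
                                    sdlog = 0.8)), 1)
  gvals <- pmin(pmax(stats::rnorm(m, 0.50, 0.05), 0.05), 0.95)
  avals <- pmax(stats::rnorm(m, 8.0e-4, 0.5e-4), 1e-4)
  fill <- function(vals) {
    M <- matrix(0, n, n)
    v <- numeric(sum(up))
    v[present] <- vals
    M[up] <- v
    M + t(M)
  }
  list(weights = fill(wvals), gfa = fill(gvals), adc = fill(avals),
       positions = pos)
}

.drawGroupVar <- function(stage, spec, min = -Inf) {
  prm <- spec[[stage]]
  if (is.null(prm)) return(NA_real_)
  pmax(stats::rnorm(1, prm[1], prm[2]), min)
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Per subject, the edge weights are the template weights times a log-normal
#' subject noise, a stage attenuation on edges internal to the planted
#' vulnerable set (and to the class-profile subsets), and multiplicative
#' age/scanner covariate factors, rounded to integer counts. gFA and ADC
#' receive diffuse per-rank shifts plus subject- and edge-level noise. The
#' processing-speed score is coupled to the z-scored vulnerable-subnetwork
#' strength. Fully deterministic given the config seed.
#'
#' @param config a [syntheticConfig()] list.
#' @return a list with \code{cohort} ([CohortConnectomes-class]),
#'   \code{subjects} (metadata \code{data.frame}) and \code{truth}
#'   ([SyntheticTruth-class]).
#' @export
generateCohort <- function(config = syntheticConfig()) {
  stopifnot(inherits(config, "syntheticConfig"))
  tpl <- buildEdgeTemplate(config, config$seed)
  n <- config$nRegions
  up <- upper.tri(tpl$weights)
  present <- tpl$weights[up] > 0
  w0 <- tpl$weights[up][present]
  g0 <- tpl$gfa[up][present]
  a0 <- tpl$adc[up][present]
  m <- length(w0)

  vuln <- sort(sample.int(n, config$vulnerableSetSize))
  shuffled <- sample(vuln)
  half <- ceiling(length(vuln) / 2)
  profA <- sort(shuffled[seq_len(half)])
  profBC <- sort(shuffled[-seq_len(half)])

  ii <- row(tpl$weights)[up][present]
  jj <- col(tpl$weights)[up][present]
  inV <- ii %in% vuln & jj %in% vuln
  inA <- ii %in% profA & jj %in% profA
  inBC <- ii %in% profBC & jj %in% profBC

  sizes <- config$groupSizes[.STAGES]
  groups <- rep(.STAGES, sizes)
  N <- length(groups)
  subjectIds <- sprintf("sub-%03d", seq_len(N))

  age <- gender <- hand <- scanner <- character(N)
  age <- numeric(N)
  for (i in seq_len(N)) {
    g <- groups[i]
    age[i] <- stats::rnorm(1, .TABLE1$age[[g]][1], .TABLE1$age[[g]][2])
    gender[i] <- if (stats::runif(1) < .TABLE1$male[[g]]) "M" else "F"
    hand[i] <- if (stats::runif(1) < .TABLE1$right[[g]]) "R" else "L"
    scanner[i] <- if (stats::runif(1) < .TABLE1$pre[[g]]) "pre" else "post"
  }
  age <- pmax(age, 18)

  W <- array(0, dim = c(n, n, N))
  G <- array(NA_real_, dim = c(n, n, N))
  A <- array(NA_real_, dim = c(n, n, N))
  clipped <- 0L
  covFactor <- numeric(N)
  upIdx <- which(up)
  for (i in seq_len(N)) {
    g <- groups[i]
    rank <- config$stageRanks[[g]]
    lf <- -config$deltaMax * rank * inV
    if (config$stageProfiles) {
      if (g == "IIIa") lf <- lf - config$profileDelta * inA
      if (g %in% c("IIIb", "IIIc")) lf <- lf - config$profileDelta * inBC
    }
    cf <- log1p(config$ageSlope) * (age[i] - 26.4) +
      log(config$scannerFactor) * (scanner[i] == "post")
    covFactor[i] <- exp(cf)
    eps <- stats::rnorm(m, 0, config$noiseSd)
    wi <- round(w0 * exp(eps + lf + cf))
    clipped <- clipped + sum(wi < 0)
    wi <- pmax(wi, 0)
    gi <- pmin(pmax(g0 - config$gfaDelta * rank +
                      stats::rnorm(1, 0, config$gfaSubjectSd) +
                      stats::rnorm(m, 0, config$gfaEdgeSd), 0.01), 0.99)
    ai <- pmax(a0 + config$adcDelta * rank +
                 stats::rnorm(1, 0, config$adcSubjectSd) +
                 stats::rnorm(m, 0, config$adcEdgeSd), 1e-5)
    gi[wi == 0] <- NA_real_
    ai[wi == 0] <- NA_real_
    Wi <- matrix(0, n, n); Gi <- matrix(NA_real_, n, n)
    Ai <- matrix(NA_real_, n, n)
    wv <- numeric(length(upIdx)); wv[present] <- wi
    Wi[upIdx] <- wv; Wi <- Wi + t(Wi)
    gv <- rep(NA_real_, length(upIdx)); gv[present] <- gi
    Gi[upIdx] <- gv; Gi[lower.tri(Gi)] <- t(Gi)[lower.tri(Gi)]
    av <- rep(NA_real_, length(upIdx)); av[present] <- ai
    Ai[upIdx] <- av; Ai[lower.tri(Ai)] <- t(Ai)[lower.tri(Ai)]
    Gi[Wi == 0] <- NA_real_
    Ai[Wi == 0] <- NA_real_
    W[, , i] <- Wi; G[, , i] <- Gi; A[, , i] <- Ai
  }
  if (clipped > 0)
    message(sprintf("%d negative computed weights clipped at 0", clipped))

  cohort <- new("CohortConnectomes", atlas = if (n == 82L) regionAtlas() else
                  data.frame(region_id = seq_len(n),
                             label = sprintf("region-%02d", seq_len(n)),
                             hemisphere = "midline",
                             tissue_class = "cortical",
                             stringsAsFactors = FALSE),
                weights = W, gfa = G, adc = A, subjectIds = subjectIds)

  vs <- subnetworkStrengths(cohort, vuln)$vulnerable_strength
  # the speed score couples to vulnerable-specific variation: the planted
  # covariate factor (shared by the whole network) is divided out, and the
  # z-score is taken within stage group so the coupling is a within-group
  # correlation with group means set by the stage shifts
  zv <- stats::ave(vs / covFactor, groups, FUN = scale)
  speed <- config$speedBase - config$speedShifts[groups] +
    config$cognitionBeta * zv + stats::rnorm(N, 0, config$cognitionNoiseSd)

  doi <- dup <- gaf <- pp <- pn <- pg <- cpz <- rep(NA_real_, N)
  for (i in seq_len(N)) {
    g <- groups[i]
    gaf[i] <- .drawGroupVar(g, .TABLE1$gaf, min = 1)
    if (g != "HC") {
      doi[i] <- .drawGroupVar(g, .TABLE1$doi, min = 0.1)
      dup[i] <- .drawGroupVar(g, .TABLE1$dup, min = 1)
      pp[i] <- .drawGroupVar(g, .TABLE1$panss_pos, min = 7)
      pn[i] <- .drawGroupVar(g, .TABLE1$panss_neg, min = 7)
      pg[i] <- .drawGroupVar(g, .TABLE1$panss_gen, min = 16)
      cpz[i] <- .drawGroupVar(g, .TABLE1$cpz, min = 0)
    }
  }
  pat <- which(groups != "HC")
  dup[sample(pat, min(12L, length(pat)))] <- NA_real_

  subjects <- data.frame(
    subject_id = subjectIds, group = groups, age = age, gender = gender,
    handedness = hand, scanner = scanner,
    processing_speed = as.numeric(speed), doi = doi, dup = dup,
    panss_pos = pp, panss_neg = pn, panss_gen = pg,
    panss_total = pp + pn + pg, gaf = gaf, cpz = cpz,
    stringsAsFactors = FALSE)

  truth <- new("SyntheticTruth", vulnerableNodes = vuln,
               stageProfiles = if (config$stageProfiles)
                 list(IIIa = profA, IIIb = profBC, IIIc = profBC)
               else list(),
               cognitionRho = config$cognitionBeta /
                 sqrt(config$cognitionBeta^2 + config$cognitionNoiseSd^2),
               config = unclass(config))
  list(cohort = cohort, subjects = subjects, truth = truth)
}

#' Recovery metrics against the planted ground truth
#'
#' @param truth a [SyntheticTruth-class] object.
#' @param scan optional [TrendScanResult-class] from the same cohort.
#' @param eval optional [DiscriminantEvaluation-class].
#' @param coupling optional correlation table from [cognitionCoupling()].
#' @return a list with vulnerable-set \code{sensitivity} and
#'   \code{specificity} (NA-flagged when the planted set is empty), the
#'   discriminant \code{loocv_error}/baselines, and the cognition-coupling
#'   recovery (\code{estimated r - planted rho} per group).
#' @export
truthReport <- function(truth, scan = NULL, eval = NULL, coupling = NULL) {
  stopifnot(methods::is(truth, "SyntheticTruth"))
  out <- list()
  if (!is.null(scan)) {
    if (nrow(scan@table) != truth@config$nRegions)
      stop("scan and truth refer to different atlases")
    tv <- truth@vulnerableNodes
    sel <- scan@vulnerable
    nReg <- truth@config$nRegions
    out$sensitivity <- if (length(tv)) length(intersect(sel, tv)) / length(tv)
      else NA_real_
    out$specificity <- if (length(tv) < nReg)
      1 - length(setdiff(sel, tv)) / (nReg - length(tv)) else NA_real_
  }
  if (!is.null(eval)) {
    out$loocv_error <- eval@loocvError
    out$baseline_chance <- eval@baselineChance
    out$baseline_naive <- eval@baselineNaive
    out$below_naive <- eval@loocvError < eval@baselineNaive
  }
  if (!is.null(coupling)) {
    v <- coupling[coupling$measure == "vulnerable", , drop = FALSE]
    out$coupling_recovery <- stats::setNames(
      v$r - truth@cognitionRho, v$group)
  }
  out
}
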