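# small in-code fixtures shared across test files

triConnectome <- function() {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 2
  w[1, 3] <- w[3, 1] <- 3
  w[2, 3] <- w[3, 2] <- 5
  Connectome(w, subjectId = "tri")
}

smallSyntheticConfig <- function(seed = 1, ...) {
  syntheticConfig(
    groupSizes = c(HC = 10, II = 4, IIIa = 4, IIIb = 4, IIIc = 4),
    nRegions = 24, vulnerableSetSize = 8, seed = seed, ...)
}

# subject table with exact group counts and simple covariates
makeSubjects <- function(sizes = c(HC = 12, II = 6, IIIa = 4, IIIb = 4,
                                   IIIc = 4), seed = 1) {
  set.seed(seed)
  groups <- rep(names(sizes), sizes)
  n <- length(groups)
  data.frame(
    subject_id = sprintf("s%03d", seq_len(n)), group = groups,
    age = rnorm(n, 26, 5),
    gender = sample(c("M", "F"), n, TRUE),
    handedness = sample(c("R", "L"), n, TRUE, prob = c(0.85, 0.15)),
    scanner = sample(c("pre", "post"), n, TRUE),
    processing_speed = rnorm(n, 47, 10),
    doi = ifelse(groups == "HC", NA, abs(rnorm(n, 3, 2))),
    gaf = rnorm(n, 70, 10),
    stringsAsFactors = FALSE)
}
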