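#' Read a square connectivity matrix from TSV
#'
#' Plain tab-separated numeric matrix, optionally preceded by comment lines
#' (\code{#}) and/or a single header row holding the region count.
#'
#' @param path file path.
#' @return numeric matrix.
#' @export
readConnectomeMatrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  first <- strsplit(lines[1], "\t")[[1]]
  if (length(first) == 1L && !is.na(suppressWarnings(as.integer(first))) &&
      length(lines) > 1L)
    lines <- lines[-1]
  m <- do.call(rbind, lapply(strsplit(lines, "\t"), function(v) {
    v[v %in% c("NA", "nan", "NaN")] <- NA_character_
    as.numeric(v)
  }))
  if (nrow(m) != ncol(m)) stop(sprintf("matrix in %s is not square", path))
  unname(m)
}

#' Read a directory of per-subject connectomes
#'
#' Expects files named \code{<subject_id>.tsv} under \code{dir}; optional
#' parallel directories provide gFA and ADC matrices with the same file
#' names.
#'
#' @param dir directory of weight matrices.
#' @param gfaDir,adcDir optional directories of per-edge scalar matrices.
#' @param atlas optional atlas \code{data.frame}.
#' @param subjectIds optional subject ordering (defaults to sorted file
#'   names).
#' @return a [CohortConnectomes-class] object.
#' @export
readConnectomeDir <- function(dir, gfaDir = NULL, adcDir = NULL,
                              atlas = NULL, subjectIds = NULL) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = FALSE))
  if (!length(files)) stop(sprintf("no .tsv connectomes found in %s", dir))
  ids <- sub("\\.tsv$", "", files)
  if (!is.null(subjectIds)) {
    miss <- setdiff(subjectIds, ids)
    if (length(miss)) stop(sprintf("connectomes missing for: %s",
                                   paste(miss, collapse = ", ")))
    ids <- subjectIds
  }
  readSet <- function(d) {
    if (is.null(d)) return(NULL)
    lapply(ids, function(id) readConnectomeMatrix(file.path(d, paste0(id, ".tsv"))))
  }
  W <- readSet(dir)
  CohortConnectomes(W, atlas = atlas, subjectIds = ids,
                    gfa = readSet(gfaDir), adc = readSet(adcDir))
}

#' Write a cohort as a directory of TSV matrices
#'
#' @param cohort a [CohortConnectomes-class] object.
#' @param dir output directory (created if needed); gFA/ADC go to
#'   \code{<dir>_gfa} and \code{<dir>_adc} siblings when present.
#' @return invisibly, the directory path.
#' @export
writeConnectomeDir <- function(cohort, dir) {
  stopifnot(methods::is(cohort, "CohortConnectomes"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dirs <- list(weights = dir)
  if (!is.null(cohort@gfa)) dirs$gfa <- paste0(sub("/$", "", dir), "_gfa")
  if (!is.null(cohort@adc)) dirs$adc <- paste0(sub("/$", "", dir), "_adc")
  for (d in dirs[-1]) dir.create(d, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nSubjects(cohort))) {
    id <- cohort@subjectIds[i]
    for (nm in names(dirs)) {
      M <- slot(cohort, nm)[, , i]
      utils::write.table(M, file.path(dirs[[nm]], paste0(id, ".tsv")),
                         sep = "\t", row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(dir)
}

#' Read a subject metadata table
#'
#' TSV with the documented column dictionary (\code{subject_id},
#' \code{group}, covariates, cognitive and clinical scores). Stage labels are
#' validated against HC, II, IIIa, IIIb, IIIc.
#'
#' @param path file path.
#' @return a validated \code{data.frame}.
#' @export
readSubjectTable <- function(path) {
  subjects <- utils::read.delim(path, stringsAsFactors = FALSE,
                                na.strings = c("NA", ""))
  .checkSubjects(subjects)
  subjects
}

#' Write a tidy table as TSV
#'
#' @param x \code{data.frame}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeTsv <- function(x, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a consistency mask as a boolean TSV matrix
#'
#' @param mask a [ConsistencyMask-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeMask <- function(mask, path) {
  stopifnot(methods::is(mask, "ConsistencyMask"))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.table(mask@retained * 1L, path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
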