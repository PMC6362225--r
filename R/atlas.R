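.DK_CORTICAL <- c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
  "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal", "lingual",
  "medialorbitofrontal", "middletemporal", "parahippocampal", "paracentral",
  "parsopercularis", "parsorbitalis", "parstriangularis", "pericalcarine",
  "postcentral", "posteriorcingulate", "precentral", "precuneus",
  "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
  "superiorparietal", "superiortemporal", "supramarginal", "frontalpole",
  "temporalpole", "transversetemporal", "insula"
)

.DK_SUBCORTICAL <- c(
  "thalamus", "caudate", "putamen", "pallidum", "hippocampus", "amygdala",
  "accumbens"
)

#' Default 82-region cortico-subcortical atlas
#'
#' Builds the region table used throughout the package: 68 cortical regions
#' (34 Desikan-Killiany parcels per hemisphere) plus 14 subcortical grey
#' matter structures (7 per hemisphere). Region indexing is 1-based and
#' contiguous.
#'
#' @return a \code{data.frame} with columns \code{region_id}, \code{label},
#'   \code{hemisphere} (\code{left}/\code{right}) and \code{tissue_class}
#'   (\code{cortical}/\code{subcortical}).
#' @examples
#' atlas <- regionAtlas()
#' table(atlas$hemisphere, atlas$tissue_class)
#' @export
regionAtlas <- function() {
  lab <- c(
    paste0("lh.", .DK_CORTICAL), paste0("rh.", .DK_CORTICAL),
    paste0("lh.", .DK_SUBCORTICAL), paste0("rh.", .DK_SUBCORTICAL)
  )
  hemi <- c(
    rep("left", length(.DK_CORTICAL)), rep("right", length(.DK_CORTICAL)),
    rep("left", length(.DK_SUBCORTICAL)), rep("right", length(.DK_SUBCORTICAL))
  )
  tis <- c(
    rep("cortical", 2L * length(.DK_CORTICAL)),
    rep("subcortical", 2L * length(.DK_SUBCORTICAL))
  )
  data.frame(
    region_id = seq_along(lab), label = lab, hemisphere = hemi,
    tissue_class = tis, stringsAsFactors = FALSE
  )
}

.checkAtlas <- function(atlas) {
  need <- c("region_id", "label", "hemisphere", "tissue_class")
  if (!is.data.frame(atlas) || !all(need %in% names(atlas)))
    return("atlas must be a data.frame with columns region_id, label, hemisphere, tissue_class")
  msg <- character()
  if (anyDuplicated(atlas$label)) msg <- c(msg, "atlas labels must be unique")
  if (!identical(as.integer(atlas$region_id), seq_len(nrow(atlas))))
    msg <- c(msg, "atlas region_id must be 1-based and contiguous")
  if (!all(atlas$hemisphere %in% c("left", "right", "midline")))
    msg <- c(msg, "atlas hemisphere must be left/right/midline")
  if (!all(atlas$tissue_class %in% c("cortical", "subcortical")))
    msg <- c(msg, "atlas tissue_class must be cortical/subcortical")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
}

#' Read a region atlas table
#'
#' Reads a TSV with columns \code{region_id}, \code{label},
#' \code{hemisphere}, \code{tissue_class}. A \code{# indexing: 0-based}
#' header comment declares 0-based region ids, which are converted to the
#' package's 1-based convention on read.
#'
#' @param path path to the atlas TSV.
#' @return validated atlas \code{data.frame}.
#' @export
readAtlas <- function(path) {
  first <- readLines(path, n = 1L)
  zero <- grepl("^#.*indexing:\\s*0-based", first)
  atlas <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE)
  if (zero) atlas$region_id <- as.integer(atlas$region_id) + 1L
  atlas$region_id <- as.integer(atlas$region_id)
  atlas <- atlas[order(atlas$region_id), , drop = FALSE]
  rownames(atlas) <- NULL
  ok <- .checkAtlas(atlas)
  if (!isTRUE(ok)) stop(ok)
  atlas
}
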