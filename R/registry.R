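#' The 18-species true-mangrove registry
#'
#' Packaged registry of the 18 true mangrove species modelled by the
#' pipeline: species codes (first letters of the binomial), family, IUCN
#' status, per-source occurrence counts (archival records and GPS-verified
#' field points), and typical intertidal position. Species codes are the
#' currency used by every stage; user-supplied registries with the same
#' columns are accepted wherever a registry is taken.
#'
#' @return A data.frame with one row per species.
#' @export
#' @examples
#' head(mangrove_species())
mangrove_species <- function() {
  path <- system.file("extdata", "mangrove_species.csv", package = "mangrest")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Published per-species evaluation scores
#'
#' Packaged fixture of per-species ensemble evaluation scores (intrinsic
#' ROC, TSS and kappa; extrinsic Boyce index) for the 18 registered
#' species, used to reproduce the reported column summaries via
#' [summarize_evaluation()].
#'
#' @return A data.frame with columns `species`, `ROC`, `TSS`, `KAPPA`,
#'   `Boyce`.
#' @export
evaluation_scores_fixture <- function() {
  path <- system.file("extdata", "evaluation_scores.csv",
                      package = "mangrest")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Conservation-status ordinal score
#'
#' LC (least concern) = 1, NT (near threatened) = 2, EN (endangered) = 3.
#'
#' @param status Character vector of IUCN codes.
#' @return Integer scores.
#' @export
iucn_score <- function(status) {
  out <- c(LC = 1L, NT = 2L, EN = 3L)[status]
  if (any(is.na(out))) stop("unknown IUCN status code", call. = FALSE)
  unname(out)
}
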