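#' Bundled curated histone sets
#'
#' Loads the curated human or Arabidopsis histone inventory shipped with
#' the package (see `inst/extdata/README.md` for provenance).  Sequences
#' are mature core histones with the documented human/Arabidopsis
#' differences; the H2B/H2A variant entries are partly synthetic
#' constructions, and the site labels are an approximate reconstruction of
#' widely reported acetylation sites (`P`) with all remaining lysines
#' labeled `N`.  Intended for demonstrations and full-inventory runs without
#' network access, not as a reference annotation.
#'
#' @param set `"human"` or `"arabidopsis"`.
#' @param filter passed to [read_histones()] (default `"strict"`).
#' @return list of `histone_protein` objects.
#' @export
curated_histones <- function(set = c("human", "arabidopsis"),
                             filter = "strict") {
  set <- match.arg(set)
  stem <- paste0("histones_", set, "_curated")
  fasta <- system.file("extdata", paste0(stem, ".fasta"),
                       package = "kacpred", mustWork = TRUE)
  sites <- system.file("extdata", paste0(stem, "_sites.tsv"),
                       package = "kacpred", mustWork = TRUE)
  read_histones(fasta, sites, filter = filter)
}
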