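#' Peptide-binding-region site map
#'
#' Loads the shipped table of peptide-binding-region amino acid positions
#' (mapped from human class II crystallography) for an exon target. The
#' table is a versioned package data file and may be replaced by the
#' user.
#'
#' @param exon_target e.g. \code{IIb_ex2}; targets absent from the table
#'   return an empty vector (the membrane-proximal exon 3 domains carry
#'   no peptide contacts).
#' @param path alternative TSV with columns \code{exon_target},
#'   \code{aa_site}.
#' @return sorted integer vector of 1-based amino acid positions.
#' @export
pbr_sites <- function(exon_target,
                      path = system.file("extdata", "pbr_sites.tsv",
                                         package = "crocmhc")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  sort(unique(tab$aa_site[tab$exon_target == exon_target]))
}
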