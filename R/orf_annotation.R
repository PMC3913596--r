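# ORF annotation: exon translation, frameshift detection against a
# functional reference, and functional / non-functional classification.
# A sequence is non-functional when it carries a premature stop codon, a
# frameshifting indel, or lacks a required conserved residue (disulfide
# bridge cysteines, peptide-termini binding sites).

#' Conserved-site specification for an exon target
#'
#' Returns the reading phase and required conserved residues for one of
#' the three amplicon targets. Defaults ship with the package
#' (\code{inst/extdata/conserved_sites.yaml}): the beta exon 3 phase is
#' chosen so the disulfide-bridge cysteines land at amino acid sites 24
#' and 80, with a CD4-binding region at sites 42-66. The exact residue
#' identities required at the termini-binding sites are package defaults
#' and fully user-auditable/overridable, since the source tables are
#' cited rather than reprinted in the literature this package follows.
#'
#' @param exon_target one of \code{IIa_ex2}, \code{IIa_ex3},
#'   \code{IIb_ex3}.
#' @param path optional alternative YAML file.
#' @return list with \code{phase}, \code{cys_pair},
#'   \code{termini_sites} (named character: site -> residue) and
#'   \code{cd4_region}.
#' @export
conserved_site_spec <- function(exon_target,
                                path = system.file("extdata",
                                                   "conserved_sites.yaml",
                                                   package = "crocmhc")) {
  all <- yaml::read_yaml(path)
  if (!exon_target %in% names(all))
    stop2("no conserved-site spec for exon target: ", exon_target)
  sp <- all[[exon_target]]
  ts <- sp$termini_sites
  list(
    exon_target = exon_target,
    phase = as.integer(sp$phase %||% 0L),
    cys_pair = as.integer(unlist(sp$cys_pair %||% integer(0))),
    termini_sites = if (length(ts))
      stats::setNames(as.character(unlist(ts)), names(ts))
      else stats::setNames(character(0), character(0)),
    cd4_region = as.integer(unlist(sp$cd4_region %||% integer(0)))
  )
}

#' Translate an exon amplicon
#'
#' Standard genetic code translation starting at \code{phase + 1}; the
#' trailing partial codon is dropped, stop codons render as \code{*}, and
#' any codon containing a gap or ambiguity code renders as \code{X}.
#'
#' @param nt_seq nucleotide string.
#' @param phase 0, 1 or 2.
#' @return amino-acid string.
#' @export
translate_exon <- function(nt_seq, phase = 0L) {
  if (!nzchar(nt_seq)) stop2("empty sequence")
  stopifnot(phase %in% 0:2)
  codons <- codon_split(toupper(nt_seq), phase = phase)
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[codons]
  aa[is.na(aa)] <- "X"  # ambiguity or gap anywhere in the codon
  paste(aa, collapse = "")
}

#' Detect frameshifting indels against a functional reference
#'
#' Globally aligns \code{nt_seq} to \code{reference} and reports every gap
#' whose length is not divisible by 3 as a frameshift, located at the
#' (1-based) amino acid site containing the first base of the gap in
#' reference coordinates. In-frame (length divisible by 3) indels are
#' reported with \code{frameshift = FALSE}.
#'
#' @param nt_seq nucleotide string.
#' @param reference functional reference variant of the same exon target.
#' @param phase reading phase of the reference.
#' @return data.frame with columns \code{kind} (insertion/deletion),
#'   \code{ref_pos}, \code{length}, \code{aa_site}, \code{frameshift}.
#' @export
detect_frameshift <- function(nt_seq, reference, phase = 0L) {
  if (is.null(reference) || !nzchar(reference))
    stop2("a functional reference variant is required for frameshift ",
          "detection; supply one via `reference`")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(toupper(nt_seq)),
    Biostrings::DNAString(toupper(reference)),
    type = "global", gapOpening = 8, gapExtension = 2)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  events <- list()
  i <- 1L; ref_pos <- 0L
  n <- length(p)
  while (i <= n) {
    if (p[i] == "-" || s[i] == "-") {
      kind <- if (p[i] == "-") "deletion" else "insertion"
      start_ref <- ref_pos + 1L  # first reference base at/after the gap
      len <- 0L
      while (i <= n && ((kind == "deletion" && p[i] == "-") ||
                        (kind == "insertion" && s[i] == "-"))) {
        if (s[i] != "-") ref_pos <- ref_pos + 1L
        len <- len + 1L
        i <- i + 1L
      }
      aa_site <- max(1L, ceiling((start_ref - phase) / 3))
      events[[length(events) + 1L]] <- data.frame(
        kind = kind, ref_pos = start_ref, length = len,
        aa_site = aa_site, frameshift = (len %% 3L) != 0L,
        stringsAsFactors = FALSE)
    } else {
      ref_pos <- ref_pos + 1L
      i <- i + 1L
    }
  }
  if (length(events)) do.call(rbind, events) else
    data.frame(kind = character(0), ref_pos = integer(0),
               length = integer(0), aa_site = integer(0),
               frameshift = logical(0))
}

#' Classify a translated exon as functional or non-functional
#'
#' Non-functional iff any premature stop codon is present, any
#' frameshifting indel was detected, or any required conserved residue
#' (cysteine pair, termini-binding sites) is absent. Reasons enumerate all
#' triggers.
#'
#' @param aa_seq amino-acid string from [translate_exon()].
#' @param indel_events data.frame from [detect_frameshift()] (or NULL).
#' @param site_spec list from [conserved_site_spec()] (or NULL to skip
#'   conserved-residue checks).
#' @return list with \code{class} (\code{functional}/\code{non_functional})
#'   and \code{reasons} (character vector).
#' @export
classify_functionality <- function(aa_seq, indel_events = NULL,
                                   site_spec = NULL) {
  reasons <- character(0)
  aa <- strsplit(aa_seq, "")[[1]]
  stops <- which(aa == "*")
  if (length(stops))
    reasons <- c(reasons, sprintf("stop_codon@%d", stops))
  if (!is.null(indel_events) && nrow(indel_events)) {
    fs <- indel_events[indel_events$frameshift, , drop = FALSE]
    if (nrow(fs))
      reasons <- c(reasons, sprintf("frameshift_%s@%d", fs$kind, fs$aa_site))
  }
  if (!is.null(site_spec)) {
    for (pos in site_spec$cys_pair) {
      if (pos > length(aa) || aa[pos] != "C")
        reasons <- c(reasons, sprintf("missing_conserved@%d", pos))
    }
    ts <- site_spec$termini_sites
    for (k in seq_along(ts)) {
      pos <- as.integer(names(ts)[k])
      if (pos > length(aa) || aa[pos] != ts[[k]])
        reasons <- c(reasons, sprintf("missing_conserved@%d", pos))
    }
  }
  list(class = if (length(reasons)) "non_functional" else "functional",
       reasons = reasons)
}

#' Annotate validated variants with functionality calls
#'
#' Translates each variant with the phase of its exon target, screens for
#' frameshifts against a reference (by default the most clone-supported
#' variant whose length matches the modal length and whose translation is
#' stop-free), and classifies functionality.
#'
#' @param variants data.frame with \code{name}, \code{seq} and
#'   \code{exon_target} columns (e.g. from [validate_clones()]).
#' @param site_specs named list of [conserved_site_spec()] results keyed
#'   by exon target; defaults are loaded for any missing target.
#' @param check_conserved logical; when FALSE only stops and frameshifts
#'   are checked (used when sequences are not in the shipped coordinate
#'   system).
#' @return the data.frame with \code{aa_seq}, \code{functionality} and
#'   \code{reasons} columns added.
#' @export
annotate_variants <- function(variants, site_specs = list(),
                              check_conserved = TRUE) {
  if (nrow(variants) == 0L) {
    variants$aa_seq <- character(0)
    variants$functionality <- character(0)
    variants$reasons <- character(0)
    return(variants)
  }
  out <- list()
  for (exon in unique(variants$exon_target)) {
    grp <- variants[variants$exon_target == exon, , drop = FALSE]
    spec <- site_specs[[exon]] %||% conserved_site_spec(exon)
    phase <- spec$phase
    grp$aa_seq <- vapply(grp$seq, translate_exon, character(1),
                         phase = phase)
    lens <- nchar(grp$seq)
    modal_len <- as.integer(names(sort(table(lens), decreasing = TRUE))[1])
    ref_idx <- which(lens == modal_len & !grepl("\\*", grp$aa_seq))
    reference <- if (length(ref_idx)) grp$seq[ref_idx[1]] else NULL
    fun <- character(nrow(grp)); rsn <- character(nrow(grp))
    for (i in seq_len(nrow(grp))) {
      indels <- NULL
      if (nchar(grp$seq[i]) != modal_len) {
        if (is.null(reference))
          stop2("no functional reference available for exon ", exon,
                "; supply sequences of the modal length or a reference")
        indels <- detect_frameshift(grp$seq[i], reference, phase = phase)
      }
      call <- classify_functionality(
        grp$aa_seq[i], indels,
        if (check_conserved) spec else NULL)
      fun[i] <- call$class
      rsn[i] <- paste(call$reasons, collapse = ";")
    }
    grp$functionality <- fun
    grp$reasons <- rsn
    out[[exon]] <- grp
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
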