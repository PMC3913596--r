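# Domain containers and file plumbing: clone reads with provenance,
# alignments, taxonomy, and result writers. Coordinates are 1-based
# inclusive throughout the package.

#' Load a species taxonomy table
#'
#' Reads a tab-separated taxonomy with columns \code{common_name},
#' \code{scientific_name}, \code{family}, \code{genus} and a four-letter
#' \code{gene_prefix} (e.g. \code{Crpo} for the saltwater crocodile).
#' The package ships a 20-species crocodylian default covering the two
#' families Crocodilidae and Alligatoridae.
#'
#' @param path path to a TSV; defaults to the shipped crocodylian table.
#' @return a data.frame of class \code{croc_taxonomy}.
#' @export
read_taxonomy <- function(path = system.file("extdata", "taxonomy.tsv",
                                             package = "crocmhc")) {
  tax <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("common_name", "scientific_name", "family", "genus", "gene_prefix")
  if (!all(req %in% names(tax)))
    stop2("taxonomy must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(tax$gene_prefix))
    stop2("gene_prefix must be unique per species")
  bad <- setdiff(tax$family, c("Crocodilidae", "Alligatoridae"))
  if (length(bad)) stop2("unknown family: ", paste(bad, collapse = ", "))
  class(tax) <- c("croc_taxonomy", "data.frame")
  tax
}

#' Read clone-amplicon FASTA with a metadata sidecar
#'
#' Clone reads travel as a standard FASTA plus a TSV keyed by FASTA record
#' id with columns \code{id}, \code{species} (gene prefix), \code{individual_id},
#' \code{pcr_id}, \code{direction} (\code{forward}/\code{reverse}) and
#' \code{exon_target} (\code{IIa_ex2}, \code{IIa_ex3} or \code{IIb_ex3}).
#'
#' @param fasta path to the FASTA file.
#' @param metadata path to the metadata TSV, or a data.frame.
#' @return data.frame of class \code{croc_reads}, one row per read, FASTA
#'   order preserved.
#' @export
read_fasta_with_metadata <- function(fasta, metadata) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  meta <- if (is.data.frame(metadata)) metadata else
    utils::read.delim(metadata, stringsAsFactors = FALSE)
  req <- c("id", "species", "individual_id", "pcr_id", "direction",
           "exon_target")
  if (!all(req %in% names(meta)))
    stop2("metadata must have columns: ", paste(req, collapse = ", "))
  ids <- names(seqs)
  missing <- setdiff(ids, meta$id)
  if (length(missing))
    stop2("metadata row missing for record(s): ",
          paste(utils::head(missing, 5), collapse = ", "))
  m <- meta[match(ids, meta$id), , drop = FALSE]
  reads <- data.frame(
    id = ids,
    species = m$species,
    individual_id = m$individual_id,
    pcr_id = m$pcr_id,
    direction = m$direction,
    exon_target = m$exon_target,
    seq = toupper(as.character(seqs)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (any(!nzchar(reads$seq))) stop2("empty sequence in FASTA")
  bad <- !vapply(reads$seq, is_iupac_nt, logical(1))
  if (any(bad))
    stop2("non-IUPAC characters in record(s): ",
          paste(utils::head(reads$id[bad], 5), collapse = ", "))
  class(reads) <- c("croc_reads", "data.frame")
  reads
}

#' Write clone reads back to FASTA + metadata TSV
#'
#' Inverse of [read_fasta_with_metadata()]; round-trips losslessly.
#'
#' @param reads a \code{croc_reads} data.frame.
#' @param fasta,metadata output paths.
#' @return invisibly, the two paths.
#' @export
write_reads <- function(reads, fasta, metadata) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, fasta, width = 70L)
  utils::write.table(
    reads[, c("id", "species", "individual_id", "pcr_id", "direction",
              "exon_target")],
    metadata, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta, metadata = metadata))
}

#' Construct an alignment object
#'
#' A thin ordered container of equal-length gapped sequences. \code{kind}
#' is one of \code{nucleotide}, \code{amino_acid} or \code{codon}; codon
#' alignments must have length divisible by 3. Columns are 1-based.
#'
#' @param records named character vector of gapped sequences.
#' @param kind alignment kind.
#' @return object of class \code{croc_alignment}.
#' @export
alignment <- function(records,
                      kind = c("nucleotide", "codon", "amino_acid")) {
  kind <- match.arg(kind)
  if (is.null(names(records)) || any(!nzchar(names(records))))
    stop2("alignment records must be named")
  records <- toupper(records)
  len <- unique(nchar(records))
  if (length(len) != 1L) stop2("alignment sequences must have equal length")
  if (kind == "codon" && len %% 3L != 0L)
    stop2("codon alignment length must be divisible by 3")
  structure(list(records = records, kind = kind, ncol = len),
            class = "croc_alignment")
}

#' @export
print.croc_alignment <- function(x, ...) {
  cat(sprintf("<croc_alignment> %s, %d sequences x %d columns\n",
              x$kind, length(x$records), x$ncol))
  invisible(x)
}

# character matrix view (rows = sequences, cols = alignment columns)
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unname(aln$records), ""))
  rownames(m) <- names(aln$records)
  m
}

# codon string matrix: rows = sequences, cols = codon sites
codon_matrix <- function(aln) {
  stopifnot(aln$kind == "codon")
  n <- aln$ncol %/% 3L
  m <- matrix(unlist(lapply(unname(aln$records), codon_split),
                     use.names = FALSE),
              nrow = length(aln$records), ncol = n, byrow = TRUE)
  rownames(m) <- names(aln$records)
  m
}

#' Read an alignment from FASTA
#' @param path FASTA file.
#' @param kind alignment kind, see [alignment()].
#' @return \code{croc_alignment}.
#' @export
read_alignment <- function(path, kind = "nucleotide") {
  set <- if (kind == "amino_acid") Biostrings::readAAStringSet(path)
         else Biostrings::readBStringSet(path)
  alignment(stats::setNames(as.character(set), names(set)), kind = kind)
}

#' Write an alignment (or named sequence set) to FASTA
#' @param x \code{croc_alignment} or named character vector.
#' @param path output path.
#' @export
write_fasta <- function(x, path) {
  records <- if (inherits(x, "croc_alignment")) x$records else x
  set <- Biostrings::BStringSet(records)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Write analysis outputs with a manifest
#'
#' Writes every table as TSV, every tree as Newick, every sequence set as
#' FASTA into \code{out_dir} and returns a manifest data.frame listing each
#' file with its row (or record/tip) count.
#'
#' @param tables named list of data.frames.
#' @param trees named list of \code{ape::phylo} objects or Newick strings.
#' @param fastas named list of named character vectors.
#' @param out_dir output directory, created if absent.
#' @return manifest data.frame (file, kind, rows).
#' @export
write_results <- function(tables = list(), trees = list(), fastas = list(),
                          out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop2("cannot create output directory: ", out_dir)
  manifest <- list()
  for (nm in names(tables)) {
    f <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(tables[[nm]], f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest[[length(manifest) + 1L]] <-
      data.frame(file = basename(f), kind = "tsv", rows = nrow(tables[[nm]]))
  }
  for (nm in names(trees)) {
    f <- file.path(out_dir, paste0(nm, ".nwk"))
    tr <- trees[[nm]]
    if (inherits(tr, "phylo")) ape::write.tree(tr, f)
    else writeLines(tr, f)
    ntip <- if (inherits(tr, "phylo")) length(tr$tip.label) else NA_integer_
    manifest[[length(manifest) + 1L]] <-
      data.frame(file = basename(f), kind = "newick", rows = ntip)
  }
  for (nm in names(fastas)) {
    f <- file.path(out_dir, paste0(nm, ".fasta"))
    write_fasta(fastas[[nm]], f)
    manifest[[length(manifest) + 1L]] <-
      data.frame(file = basename(f), kind = "fasta",
                 rows = length(fastas[[nm]]))
  }
  if (length(manifest) == 0L)
    return(data.frame(file = character(0), kind = character(0),
                      rows = integer(0)))
  do.call(rbind, manifest)
}
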