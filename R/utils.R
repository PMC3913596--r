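# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom Biostrings IUPAC_CODE_MAP
iupac_bases <- function(x) {
  # base sets of IUPAC nucleotide codes; '-' and '.' treated as gap (empty set)
  map <- Biostrings::IUPAC_CODE_MAP
  out <- strsplit(unname(map[x]), "")
  out[is.na(map[x])] <- list(character(0))
  out
}

is_iupac_nt <- function(seq) {
  ok <- c(names(Biostrings::IUPAC_CODE_MAP), "-", ".")
  all(strsplit(toupper(seq), "")[[1]] %in% ok)
}

#' Reverse complement of an IUPAC nucleotide string
#' @param seq character scalar.
#' @return character scalar.
#' @keywords internal
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# intersection of two IUPAC codes, NA if incompatible
iupac_intersect <- function(a, b) {
  map <- Biostrings::IUPAC_CODE_MAP
  sa <- strsplit(map[[a]], "")[[1]]
  sb <- strsplit(map[[b]], "")[[1]]
  common <- intersect(sa, sb)
  if (length(common) == 0L) return(NA_character_)
  key <- paste(sort(common), collapse = "")
  names(map)[match(key, vapply(strsplit(map, ""), function(s)
    paste(sort(s), collapse = ""), ""))]
}

# split a nucleotide string into codons (trailing partial codon dropped)
codon_split <- function(seq, phase = 0L) {
  s <- substr(seq, phase + 1L, nchar(seq))
  n <- nchar(s) %/% 3L
  if (n == 0L) return(character(0))
  substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# deterministic per-stage seed derivation (kept below 2^31)
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offset <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}

stop2 <- function(...) stop(..., call. = FALSE)
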