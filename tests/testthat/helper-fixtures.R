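# Fixture builders and independent oracles used across the suite.
# Everything is generated in code; no binary fixtures.

SENSE_CODONS <- {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

random_codon_seq <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(SENSE_CODONS, n_codons, replace = TRUE), collapse = "")
}

# a minimal two-species taxonomy for unit tests
toy_taxonomy <- function() {
  tax <- data.frame(
    common_name = c("Saltwater crocodile", "Spectacled caiman"),
    scientific_name = c("Crocodylus porosus", "Caiman crocodylus"),
    family = c("Crocodilidae", "Alligatoridae"),
    genus = c("Crocodylus", "Caiman"),
    gene_prefix = c("Crpo", "Cacr"),
    stringsAsFactors = FALSE)
  class(tax) <- c("croc_taxonomy", "data.frame")
  tax
}

# clone reads (fwd + rev) for a named list of clone sequences
make_reads <- function(clone_seqs, species, individual, pcr,
                       exon = "IIb_ex3") {
  rows <- list()
  for (cl in names(clone_seqs)) {
    s <- clone_seqs[[cl]]
    rows[[length(rows) + 1L]] <- data.frame(
      id = paste0(cl, "_F"), species = species, individual_id = individual,
      pcr_id = pcr, direction = "forward", exon_target = exon, seq = s,
      clone_id = cl, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      id = paste0(cl, "_R"), species = species, individual_id = individual,
      pcr_id = pcr, direction = "reverse", exon_target = exon,
      seq = crocmhc:::revcomp(s), clone_id = cl, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("croc_reads", "data.frame")
  out
}

# ---- independent NG86 oracle (path enumeration) ----

oracle_syn_sites <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (pos in 1:3) {
    alts <- vapply(setdiff(bases, substr(codon, pos, pos)), function(b) {
      x <- codon; substr(x, pos, pos) <- b; x
    }, character(1))
    alts <- alts[gc[alts] != "*"]
    if (length(alts)) s <- s + mean(gc[alts] == gc[[codon]])
  }
  s
}

all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in all_perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

oracle_path_counts <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  diffs <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(diffs) == 0L) return(c(sd = 0, nd = 0))
  walk <- function(order, allow_stop) {
    cur <- c1; sd <- 0; nd <- 0
    for (pos in order) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (gc[[nxt]] == "*" && !allow_stop) return(NULL)
      syn <- gc[[nxt]] != "*" && gc[[cur]] != "*" &&
        gc[[nxt]] == gc[[cur]]
      if (syn) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  paths <- Filter(Negate(is.null),
                  lapply(all_perms(diffs), walk, allow_stop = FALSE))
  if (length(paths) == 0L)
    paths <- lapply(all_perms(diffs), walk, allow_stop = TRUE)
  colMeans(do.call(rbind, paths))
}

oracle_ng86 <- function(seq1, seq2) {
  c1 <- substring(seq1, seq(1, nchar(seq1), 3), seq(3, nchar(seq1), 3))
  c2 <- substring(seq2, seq(1, nchar(seq2), 3), seq(3, nchar(seq2), 3))
  stops <- c("TAA", "TAG", "TGA")
  ok <- grepl("^[ACGT]{3}$", c1) & grepl("^[ACGT]{3}$", c2) &
    !(c1 %in% stops) & !(c2 %in% stops)
  c1 <- c1[ok]; c2 <- c2[ok]
  if (!length(c1)) return(list(nd = NA, sd = NA, N = NA, S = NA))
  S <- (sum(vapply(c1, oracle_syn_sites, numeric(1))) +
          sum(vapply(c2, oracle_syn_sites, numeric(1)))) / 2
  counts <- vapply(seq_along(c1), function(k)
    oracle_path_counts(c1[k], c2[k]), numeric(2))
  list(nd = sum(counts["nd", ]), sd = sum(counts["sd", ]),
       N = 3 * length(c1) - S, S = S)
}

# brute-force single-crossover chimera check
oracle_is_chimera <- function(v, others) {
  L <- nchar(v)
  for (p1 in others) for (p2 in others) {
    if (identical(p1, p2) || nchar(p1) != L || nchar(p2) != L) next
    for (k in 1:(L - 1)) {
      comp <- paste0(substr(p1, 1, k), substr(p2, k + 1, L))
      if (comp == v && v != p1 && v != p2) return(TRUE)
    }
  }
  FALSE
}

# fast simulation config for tests (single beta target)
test_sim_config <- function(...) {
  sim_config(targets = list(IIb_ex3 = list(length = 260L, loci = 2L,
                                           phase = 2L)), ...)
}
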