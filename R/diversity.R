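# Molecular diversity: pairwise nucleotide differences and Nei-Gojobori
# (NG86) synonymous/nonsynonymous counting with equal-path averaging and
# Jukes-Cantor correction.
#
# Conventions (documented because NG86 variants differ):
# * site counts per codon position are fractions of the non-stop single-
#   nucleotide changes that are synonymous, so n + s = 3 per codon;
# * codons containing gaps/ambiguity, and stop codons themselves, are
#   skipped pairwise (pairwise deletion, MEGA-like);
# * mutational paths passing through a stop codon are excluded from the
#   equal-weight path average; if every path is blocked, all paths are
#   used with steps into/out of stops counted as nonsynonymous.

.ng86_env <- new.env(parent = emptyenv())

ng86_tables <- function() {
  if (!is.null(.ng86_env$sites)) return(.ng86_env)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  bases <- c("A", "C", "G", "T")
  syn_sites <- stats::setNames(numeric(length(codons)), codons)
  for (cd in codons) {
    if (gc[[cd]] == "*") { syn_sites[cd] <- NA_real_; next }
    s <- 0
    for (pos in 1:3) {
      alt <- vapply(setdiff(bases, substr(cd, pos, pos)), function(b) {
        x <- cd; substr(x, pos, pos) <- b; x
      }, character(1))
      keep <- gc[alt] != "*"
      if (!any(keep)) next  # cannot happen for sense codons
      s <- s + sum(gc[alt[keep]] == gc[[cd]]) / sum(keep)
    }
    syn_sites[cd] <- s
  }
  .ng86_env$sites <- syn_sites
  .ng86_env$gc <- gc
  .ng86_env$path_cache <- new.env(parent = emptyenv())
  .ng86_env
}

# equal-weight path average of (synonymous, nonsynonymous) step counts
# between two sense codons
ng86_path_counts <- function(c1, c2) {
  env <- ng86_tables()
  key <- paste(c1, c2)
  hit <- env$path_cache[[key]]
  if (!is.null(hit)) return(hit)
  gc <- env$gc
  diffs <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  d <- length(diffs)
  if (d == 0L) {
    res <- c(sd = 0, nd = 0)
  } else {
    perms <- if (d == 1L) list(diffs)
      else if (d == 2L) list(diffs, rev(diffs))
      else {
        p <- list()
        for (i in 1:3) for (j in setdiff(1:3, i))
          p[[length(p) + 1L]] <- diffs[c(i, j, setdiff(1:3, c(i, j)))]
        p
      }
    score <- function(path, allow_stop) {
      cur <- c1; sd <- 0; nd <- 0
      for (pos in path) {
        nxt <- cur
        substr(nxt, pos, pos) <- substr(c2, pos, pos)
        if (gc[[nxt]] == "*" && !allow_stop) return(NULL)
        if (gc[[nxt]] == "*" || gc[[cur]] == "*" ||
            gc[[nxt]] != gc[[cur]]) nd <- nd + 1 else sd <- sd + 1
        cur <- nxt
      }
      c(sd = sd, nd = nd)
    }
    scored <- Filter(Negate(is.null), lapply(perms, score,
                                             allow_stop = FALSE))
    if (length(scored) == 0L)
      scored <- lapply(perms, score, allow_stop = TRUE)
    res <- colMeans(do.call(rbind, scored))
  }
  env$path_cache[[key]] <- res
  res
}

# TRUE for codons that are scoreable: plain ACGT, sense codon
codon_scoreable <- function(cd) {
  grepl("^[ACGT]{3}$", cd) & !(cd %in% c("TAA", "TAG", "TGA"))
}

#' Pairwise nucleotide differences
#'
#' Entry (i, j) is the number of alignment columns where sequences i and j
#' carry different non-gap characters.
#'
#' @param aln a nucleotide \code{croc_alignment}.
#' @return symmetric integer matrix with zero diagonal.
#' @export
pairwise_differences <- function(aln) {
  m <- aln_matrix(aln)
  n <- nrow(m)
  out <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  gap <- c("-", ".")
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !(m[i, ] %in% gap) & !(m[j, ] %in% gap)
    out[i, j] <- out[j, i] <- sum(m[i, ok] != m[j, ok])
  }
  out
}

# NG86 for one codon pair vector (character vectors of codons)
ng86_pair <- function(cd1, cd2) {
  env <- ng86_tables()
  ok <- codon_scoreable(cd1) & codon_scoreable(cd2)
  cd1 <- cd1[ok]; cd2 <- cd2[ok]
  if (length(cd1) == 0L)
    return(list(nd = NA_real_, sd = NA_real_, N = NA_real_, S = NA_real_,
                n_codons = 0L))
  s1 <- sum(env$sites[cd1]); s2 <- sum(env$sites[cd2])
  S <- (s1 + s2) / 2
  N <- 3 * length(cd1) - S
  counts <- vapply(seq_along(cd1), function(k)
    ng86_path_counts(cd1[k], cd2[k]), numeric(2))
  list(nd = sum(counts["nd", ]), sd = sum(counts["sd", ]),
       N = N, S = S, n_codons = length(cd1))
}

jc_correct <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p) & p < 0.75
  out[ok] <- -0.75 * log(1 - 4 * p[ok] / 3)
  out
}

#' Nei-Gojobori synonymous/nonsynonymous analysis
#'
#' NG86 counting with equal-path averaging and Jukes-Cantor correction
#' for every sequence pair of a codon alignment, optionally restricted to
#' a subset of codon columns (e.g. the peptide-binding region).
#'
#' @param aln a codon \code{croc_alignment} (length divisible by 3).
#' @param subset optional integer vector of 1-based codon-column indices.
#' @return data.frame of class \code{ng86_pairs}: one row per pair with
#'   \code{seq_a}, \code{seq_b}, \code{nd}, \code{sd}, \code{N_sites},
#'   \code{S_sites}, \code{pN}, \code{pS}, \code{dN}, \code{dS};
#'   attribute \code{means} holds the across-pair means.
#' @export
nei_gojobori <- function(aln, subset = NULL) {
  cm <- codon_matrix(aln)
  if (!is.null(subset)) {
    if (any(subset < 1L | subset > ncol(cm)))
      stop2("subset indices out of range")
    cm <- cm[, subset, drop = FALSE]
  }
  n <- nrow(cm)
  if (n < 2L) stop2("need at least two sequences")
  rows <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    r <- ng86_pair(cm[i, ], cm[j, ])
    pN <- r$nd / r$N; pS <- r$sd / r$S
    rows[[length(rows) + 1L]] <- data.frame(
      seq_a = rownames(cm)[i], seq_b = rownames(cm)[j],
      nd = r$nd, sd = r$sd, N_sites = r$N, S_sites = r$S,
      pN = pN, pS = pS, dN = jc_correct(pN), dS = jc_correct(pS),
      n_codons = r$n_codons, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "means") <- c(dN = mean(out$dN, na.rm = TRUE),
                          dS = mean(out$dS, na.rm = TRUE),
                          pN = mean(out$pN, na.rm = TRUE),
                          pS = mean(out$pS, na.rm = TRUE))
  class(out) <- c("ng86_pairs", "data.frame")
  out
}
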