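# Recombination screening: a max-chi-square breakpoint scan over sequence
# pairs, a triplet-incongruence scan, and an exact chimera-composition
# test, combined by a consensus rule (call accepted when detected by at
# least two detectors with consensus score > 60). Population-scaled rates:
# Watterson theta per alignment and a grid-based composite-likelihood rho.

# max chi-square split of a binary vector over candidate breakpoints,
# using a window of `w` informative sites on each side
max_chi_split <- function(x, w) {
  M <- length(x)
  if (M < 2L * w) return(list(stat = 0, k = NA_integer_))
  cs <- c(0, cumsum(x))
  best <- 0; best_k <- NA_integer_
  for (k in w:(M - w)) {
    a <- cs[k + 1L] - cs[k - w + 1L]        # mismatches in left window
    b <- cs[k + w + 1L] - cs[k + 1L]        # mismatches in right window
    n1 <- w; n2 <- w
    tot <- a + b
    if (tot == 0L || tot == n1 + n2) next
    e1 <- n1 * tot / (n1 + n2); e2 <- n2 * tot / (n1 + n2)
    f1 <- n1 - e1; f2 <- n2 - e2
    chi <- (a - e1)^2 / e1 + (b - e2)^2 / e2 +
      ((n1 - a) - f1)^2 / f1 + ((n2 - b) - f2)^2 / f2
    if (chi > best) { best <- chi; best_k <- k }
  }
  list(stat = best, k = best_k)
}

#' Max-chi-square recombination scan
#'
#' For every sequence pair, scans candidate breakpoints for a maximal
#' chi-square contrast in the density of pairwise differences left versus
#' right of the breakpoint (windows of \code{window} variable sites each
#' side). Significance by permutation of the variable columns, Bonferroni
#' adjusted over pairs.
#'
#' @param aln nucleotide \code{croc_alignment} with >= 3 sequences.
#' @param window half-window in variable sites; default
#'   \code{max(5, floor(M/5))} for M variable sites of a pair.
#' @param permutations permutation replicates (default 1000).
#' @param seed integer seed.
#' @param alpha significance cut-off applied to adjusted p-values.
#' @return data.frame: \code{seq_a}, \code{seq_b}, \code{breakpoint}
#'   (alignment column), \code{chi2}, \code{p_raw}, \code{p_adj},
#'   \code{significant}; 0 rows when there are no polymorphic sites.
#' @export
maxchi_scan <- function(aln, window = NULL, permutations = 1000L,
                        seed = 1L, alpha = 0.05) {
  m <- aln_matrix(aln)
  if (nrow(m) < 3L) stop2("need at least 3 sequences")
  out <- data.frame(seq_a = character(0), seq_b = character(0),
                    breakpoint = integer(0), chi2 = numeric(0),
                    p_raw = numeric(0), p_adj = numeric(0),
                    significant = logical(0), stringsAsFactors = FALSE)
  gap <- c("-", ".", "N")
  variable <- apply(m, 2, function(col) {
    b <- col[!col %in% gap]; length(unique(b)) > 1L
  })
  if (!any(variable)) return(out)
  n <- nrow(m)
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- variable & !(m[i, ] %in% gap) & !(m[j, ] %in% gap)
    cols <- which(ok)
    x <- as.integer(m[i, cols] != m[j, cols])
    M <- length(x)
    if (M < 4L || sum(x) == 0L || sum(x) == M) next
    w <- window %||% max(5L, floor(M / 5))
    obs <- max_chi_split(x, w)
    if (!is.finite(obs$stat) || obs$stat == 0) next
    null <- vapply(seq_len(permutations), function(r)
      max_chi_split(sample(x), w)$stat, numeric(1))
    p <- (1 + sum(null >= obs$stat)) / (permutations + 1)
    rows[[length(rows) + 1L]] <- data.frame(
      seq_a = rownames(m)[i], seq_b = rownames(m)[j],
      breakpoint = cols[obs$k], chi2 = obs$stat, p_raw = p,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(out)
  res <- do.call(rbind, rows)
  res$p_adj <- pmin(1, res$p_raw * nrow(res))
  res$significant <- res$p_adj < alpha
  res
}

#' Triplet-incongruence recombination scan
#'
#' For each putative recombinant, takes its two nearest neighbours as
#' candidate parents, records at parent-informative sites which parent
#' the sequence matches, and scans for a breakpoint-like switch of
#' allegiance with the same max-chi-square machinery and permutation null
#' as [maxchi_scan()]. Bonferroni adjusted over sequences.
#'
#' @inheritParams maxchi_scan
#' @return data.frame: \code{recombinant}, \code{parent1}, \code{parent2},
#'   \code{breakpoint}, \code{chi2}, \code{p_raw}, \code{p_adj},
#'   \code{significant}.
#' @export
triplet_scan <- function(aln, window = NULL, permutations = 1000L,
                         seed = 1L, alpha = 0.05) {
  m <- aln_matrix(aln)
  if (nrow(m) < 3L) stop2("need at least 3 sequences")
  out <- data.frame(recombinant = character(0), parent1 = character(0),
                    parent2 = character(0), breakpoint = integer(0),
                    chi2 = numeric(0), p_raw = numeric(0),
                    p_adj = numeric(0), significant = logical(0),
                    stringsAsFactors = FALSE)
  gap <- c("-", ".", "N")
  n <- nrow(m)
  D <- matrix(Inf, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    D[i, j] <- D[j, i] <- sum(m[i, ] != m[j, ])
  set.seed(seed)
  rows <- list()
  for (r in seq_len(n)) {
    ord <- order(D[r, ])
    cand <- setdiff(ord, r)
    if (length(cand) < 2L) next
    p1 <- cand[1]; p2 <- cand[2]
    ok <- !(m[r, ] %in% gap) & !(m[p1, ] %in% gap) &
      !(m[p2, ] %in% gap) & (m[p1, ] != m[p2, ])
    cols <- which(ok & (m[r, ] == m[p1, ] | m[r, ] == m[p2, ]))
    if (length(cols) < 4L) next
    x <- as.integer(m[r, cols] == m[p1, cols])
    if (sum(x) == 0L || sum(x) == length(x)) next
    w <- window %||% max(5L, floor(length(x) / 5))
    obs <- max_chi_split(x, w)
    if (!is.finite(obs$stat) || obs$stat == 0) next
    null <- vapply(seq_len(permutations), function(k)
      max_chi_split(sample(x), w)$stat, numeric(1))
    p <- (1 + sum(null >= obs$stat)) / (permutations + 1)
    rows[[length(rows) + 1L]] <- data.frame(
      recombinant = rownames(m)[r], parent1 = rownames(m)[p1],
      parent2 = rownames(m)[p2], breakpoint = cols[obs$k], chi2 = obs$stat,
      p_raw = p, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(out)
  res <- do.call(rbind, rows)
  res$p_adj <- pmin(1, res$p_raw * nrow(res))
  res$significant <- res$p_adj < alpha
  res
}

#' Exact chimera-composition scan across an alignment
#'
#' Generalizes the within-individual chimera test: a sequence is flagged
#' when it is exactly a single-crossover combination of two other
#' sequences of the alignment.
#'
#' @param aln nucleotide \code{croc_alignment}.
#' @return data.frame: \code{recombinant}, \code{parent1}, \code{parent2},
#'   \code{breakpoint_lo}, \code{breakpoint_hi}, \code{significant}.
#' @export
composition_scan <- function(aln) {
  flags <- detect_within_individual_chimeras(aln$records)
  data.frame(recombinant = flags$name, parent1 = flags$parent1,
             parent2 = flags$parent2, breakpoint_lo = flags$k_min,
             breakpoint_hi = flags$k_max,
             significant = rep(TRUE, nrow(flags)),
             stringsAsFactors = FALSE)
}

#' Consensus recombination call
#'
#' Combines per-detector outputs: a sequence is called recombinant only
#' when at least \code{min_detectors} detectors flagged it and the
#' consensus score exceeds \code{min_score}. The score is
#' \code{100 * (supporting / run) * median(support)} where a detector's
#' support is \code{1 - p_adj} (1 for the exact composition test).
#'
#' @param maxchi,triplet,composition detector outputs (any may be NULL,
#'   but at least two detectors must have been run).
#' @param min_detectors minimum number of supporting detectors (default 2).
#' @param min_score minimum consensus score, strict (default 60).
#' @return data.frame of accepted calls: \code{recombinant},
#'   \code{parents}, \code{breakpoint}, \code{detectors},
#'   \code{consensus_score}.
#' @export
consensus_recombination_call <- function(maxchi = NULL, triplet = NULL,
                                         composition = NULL,
                                         min_detectors = 2L,
                                         min_score = 60) {
  ran <- list(maxchi = maxchi, triplet = triplet,
              composition = composition)
  ran <- ran[!vapply(ran, is.null, logical(1))]
  if (length(ran) < 2L)
    stop2("consensus calling needs at least two detectors run")
  # per-sequence evidence across detectors
  ev <- list()
  add <- function(det, seqs, support, parents, bp) {
    for (k in seq_along(seqs)) {
      s <- seqs[k]
      e <- ev[[s]] %||% list(detectors = character(0),
                             support = numeric(0),
                             parents = character(0), bp = integer(0))
      e$detectors <- c(e$detectors, det)
      e$support <- c(e$support, support[k])
      e$parents <- c(e$parents, parents[k])
      e$bp <- c(e$bp, bp[k])
      ev[[s]] <<- e
    }
  }
  if (!is.null(maxchi) && nrow(maxchi)) {
    sig <- maxchi[maxchi$significant, , drop = FALSE]
    if (nrow(sig)) {
      # a pairwise hit implicates both sequences; keep the best per sequence
      for (s in unique(c(sig$seq_a, sig$seq_b))) {
        hits <- sig[sig$seq_a == s | sig$seq_b == s, , drop = FALSE]
        best <- hits[which.min(hits$p_adj), ]
        add("maxchi", s, 1 - best$p_adj,
            paste(best$seq_a, best$seq_b, sep = "/"), best$breakpoint)
      }
    }
  }
  if (!is.null(triplet) && nrow(triplet)) {
    sig <- triplet[triplet$significant, , drop = FALSE]
    if (nrow(sig)) add("triplet", sig$recombinant, 1 - sig$p_adj,
                       paste(sig$parent1, sig$parent2, sep = "/"),
                       sig$breakpoint)
  }
  if (!is.null(composition) && nrow(composition)) {
    add("composition", composition$recombinant,
        rep(1, nrow(composition)),
        paste(composition$parent1, composition$parent2, sep = "/"),
        floor((composition$breakpoint_lo + composition$breakpoint_hi) / 2))
  }
  rows <- list()
  for (s in names(ev)) {
    e <- ev[[s]]
    k <- length(unique(e$detectors))
    score <- 100 * (k / length(ran)) * stats::median(e$support)
    if (k >= min_detectors && score > min_score) {
      rows[[length(rows) + 1L]] <- data.frame(
        recombinant = s,
        parents = e$parents[which.max(e$support)],
        breakpoint = e$bp[which.max(e$support)],
        detectors = paste(unique(e$detectors), collapse = ","),
        consensus_score = score, stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(recombinant = character(0), parents = character(0),
               breakpoint = integer(0), detectors = character(0),
               consensus_score = numeric(0))
}

#' Watterson theta and composite-likelihood rho
#'
#' \code{theta} is the Watterson estimator S / a_(n-1) per alignment
#' (S segregating sites, a_(n-1) = sum of 1/i). \code{rho} (4Nec across
#' the sequence length) maximises a pairwise composite likelihood of
#' four-gamete violations over a fixed grid (0 plus 50 log-spaced points
#' on [0.01, 100]): for segregating-site pairs at distance d, the
#' probability that a recombination event separates them in the sample
#' history is modelled as 1 - exp(-rho * d/L * a_(n-1)). This is a stated
#' operational stand-in for full two-locus coalescent likelihoods; with
#' no four-gamete violations the estimate sits at the grid minimum.
#'
#' @param aln nucleotide \code{croc_alignment}, >= 4 sequences.
#' @param max_pairs cap on the number of site pairs scored (subsampled
#'   deterministically if exceeded).
#' @return list of class \code{recomb_estimates}: \code{rho},
#'   \code{theta}, \code{n_segregating}, \code{ratio_note}.
#' @export
estimate_rho_theta <- function(aln, max_pairs = 5000L) {
  m <- aln_matrix(aln)
  n <- nrow(m)
  if (n < 4L) stop2("need at least 4 sequences")
  gap <- c("-", ".", "N")
  seg <- which(apply(m, 2, function(col) {
    b <- col[!col %in% gap]
    length(unique(b)) > 1L
  }))
  a_n <- sum(1 / seq_len(n - 1L))
  theta <- length(seg) / a_n
  grid <- c(0, exp(seq(log(0.01), log(100), length.out = 50)))
  if (length(seg) < 2L) {
    res <- list(rho = 0, theta = theta, n_segregating = length(seg),
                ratio_note = "low recombination (rho < theta)")
    class(res) <- "recomb_estimates"
    return(res)
  }
  # biallelic segregating sites only
  biall <- seg[vapply(seg, function(j) {
    b <- m[, j][!m[, j] %in% gap]
    length(unique(b)) == 2L
  }, logical(1))]
  pairs <- if (length(biall) >= 2L) utils::combn(biall, 2L) else
    matrix(integer(0), 2, 0)
  if (ncol(pairs) > max_pairs)
    pairs <- pairs[, floor(seq(1, ncol(pairs), length.out = max_pairs)),
                   drop = FALSE]
  L <- ncol(m)
  viol <- logical(ncol(pairs)); dist <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    ok <- !(m[, i] %in% gap) & !(m[, j] %in% gap)
    haps <- unique(paste(m[ok, i], m[ok, j]))
    viol[k] <- length(haps) == 4L
    dist[k] <- (j - i) / L
  }
  ll <- vapply(grid, function(rho) {
    p <- 1 - exp(-rho * dist * a_n)
    p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    sum(ifelse(viol, log(p), log(1 - p)))
  }, numeric(1))
  rho <- grid[which.max(ll)]
  res <- list(rho = rho, theta = theta, n_segregating = length(seg),
              grid = grid, loglik = ll,
              ratio_note = if (rho < theta)
                "low recombination (rho < theta)" else
                "rho >= theta")
  class(res) <- "recomb_estimates"
  res
}

#' @export
print.recomb_estimates <- function(x, ...) {
  cat(sprintf("rho = %.4g, theta = %.4g (%d segregating sites); %s\n",
              x$rho, x$theta, x$n_segregating, x$ratio_note))
  invisible(x)
}
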