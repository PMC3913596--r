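# Clone-sampling coverage model: with m distinct variants present in an
# individual's PCR template pool (sampled with frequencies p), how
# informative are n sequenced clones? Both the probability that every
# variant is observed and the expected fraction of variants observed are
# exposed; a diploid two-locus preset (four equifrequent haplotypes) is
# the shipped default for class II beta.

check_freqs <- function(m, p) {
  if (is.null(p)) p <- rep(1 / m, m)
  if (length(p) != m || any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop2("p must be ", m, " nonnegative frequencies summing to 1")
  p
}

#' Probability that all variants are detected
#'
#' Inclusion-exclusion over variant subsets:
#' sum over S of (-1)^|S| (1 - sum_{i in S} p_i)^n. Zero whenever
#' \code{n < m}.
#'
#' @param m number of distinct variants (>= 1).
#' @param n number of clones sequenced (>= 0).
#' @param p sampling frequencies (default equal).
#' @return probability in [0, 1].
#' @export
prob_all_detected <- function(m, n, p = NULL) {
  stopifnot(m >= 1, n >= 0)
  p <- check_freqs(m, p)
  if (n < m) return(0)
  total <- 0
  for (k in 0:m) {
    subsets <- utils::combn(m, k)
    if (k == 0L) { total <- total + 1; next }
    mass <- 1 - colSums(matrix(p[subsets], nrow = k))
    total <- total + (-1)^k * sum(pmax(mass, 0)^n)
  }
  min(max(total, 0), 1)
}

#' Expected fraction of variants detected
#'
#' \code{sum_i (1 - (1 - p_i)^n) / m}.
#'
#' @inheritParams prob_all_detected
#' @return expected fraction in [0, 1].
#' @export
expected_fraction_detected <- function(m, n, p = NULL) {
  stopifnot(m >= 1, n >= 0)
  p <- check_freqs(m, p)
  sum(1 - (1 - p)^n) / m
}

#' Minimum clone count for a detection confidence
#'
#' Smallest n with \code{prob_all_detected(m, n, p) >= confidence};
#' exact by incrementing n (the probability is nondecreasing in n).
#'
#' @param m number of variants.
#' @param confidence target probability in (0, 1).
#' @param p sampling frequencies (default equal).
#' @param n_max safety cap.
#' @return integer n.
#' @export
min_clones_for_confidence <- function(m, confidence, p = NULL,
                                      n_max = 10000L) {
  stopifnot(confidence > 0, confidence < 1)
  p <- check_freqs(m, p)
  n <- m
  while (n <= n_max) {
    if (prob_all_detected(m, n, p) >= confidence) return(n)
    n <- n + 1L
  }
  stop2("confidence not reached within n_max clones")
}
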