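# small alignments and permutation counts keep this fast; the null
# false-positive-rate criterion runs in test-acceptance.R

divergent_parents <- function(n_codons = 80, seed = 1) {
  tr <- ape::read.tree(text = "(p1:0.17,p2:0.17);")  # ~10% nt divergence
  ev <- evolve_codon_sequences(tr, n_codons, omega = 1, seed = seed)
  ev$leaf
}

test_that("maxchi finds planted breakpoints in half/half chimeras", {
  hits <- 0L
  for (sd in 1:3) {
    par <- divergent_parents(seed = sd)
    L <- nchar(par[[1]])
    bp <- L %/% 2
    chim <- paste0(substr(par[["p1"]], 1, bp),
                   substr(par[["p2"]], bp + 1, L))
    # background relatives so the scan has >= 3 sequences
    aln <- alignment(c(par, chimera = chim), kind = "nucleotide")
    res <- maxchi_scan(aln, permutations = 200, seed = sd)
    sig <- res[res$significant & (res$seq_a == "chimera" |
                                    res$seq_b == "chimera"), ]
    if (nrow(sig) && any(abs(sig$breakpoint - bp) < 60)) hits <- hits + 1L
  }
  expect_gte(hits, 2L)
})

test_that("maxchi returns nothing without polymorphism", {
  s <- random_codon_seq(40, seed = 15)
  aln <- alignment(stats::setNames(rep(s, 4), paste0("s", 1:4)))
  expect_equal(nrow(maxchi_scan(aln, permutations = 50, seed = 1)), 0L)
  expect_error(maxchi_scan(alignment(c(a = s, b = s)), permutations = 10),
               "at least 3")
})

test_that("triplet scan flags the recombinant, not the parents", {
  par <- divergent_parents(seed = 9)
  L <- nchar(par[[1]])
  bp <- L %/% 2
  chim <- paste0(substr(par[["p1"]], 1, bp), substr(par[["p2"]], bp + 1, L))
  aln <- alignment(c(par, chimera = chim), kind = "nucleotide")
  res <- triplet_scan(aln, permutations = 200, seed = 2)
  sig <- res[res$significant, ]
  expect_true("chimera" %in% sig$recombinant)
})

test_that("consensus rule enforces detector count and score thresholds", {
  mk <- function(sig) data.frame(
    recombinant = "x", parent1 = "a", parent2 = "b", breakpoint = 50L,
    chi2 = 10, p_raw = if (sig) 0.001 else 0.9,
    p_adj = if (sig) 0.003 else 1, significant = sig,
    stringsAsFactors = FALSE)
  comp <- data.frame(recombinant = "x", parent1 = "a", parent2 = "b",
                     breakpoint_lo = 40L, breakpoint_hi = 60L,
                     significant = TRUE, stringsAsFactors = FALSE)
  # 1 of 3 detectors fires: no call
  none <- consensus_recombination_call(
    maxchi = transform(mk(FALSE), seq_a = "x", seq_b = "a"),
    triplet = mk(FALSE), composition = comp)
  expect_equal(nrow(none), 0L)
  # 3 of 3 fire with strong support: score near 100
  mx <- mk(TRUE); mx$seq_a <- "x"; mx$seq_b <- "a"
  all3 <- consensus_recombination_call(maxchi = mx, triplet = mk(TRUE),
                                       composition = comp)
  expect_equal(nrow(all3), 1L)
  expect_gt(all3$consensus_score, 99)
  # accepted calls satisfy both thresholds by construction
  expect_true(all(all3$consensus_score > 60))
  # single detector is an error
  expect_error(consensus_recombination_call(triplet = mk(TRUE)),
               "two detectors")
})

test_that("rho/theta estimates: closed form and degenerate input", {
  aln <- alignment(c(a = "ACGTA", b = "ACGTC", c = "AGGTC", d = "TCGTC"))
  est <- estimate_rho_theta(aln)
  expect_equal(est$theta, 3 / (1 + 1 / 2 + 1 / 3), tolerance = 1e-9)

  s <- random_codon_seq(20, seed = 16)
  mono <- alignment(stats::setNames(rep(s, 4), paste0("s", 1:4)))
  est0 <- estimate_rho_theta(mono)
  expect_equal(est0$theta, 0)
  expect_equal(est0$rho, 0)
  expect_match(est0$ratio_note, "low recombination")
  expect_error(estimate_rho_theta(alignment(c(a = s, b = s, c = s))),
               "at least 4")
})

test_that("clonal (tree-like) alignments put rho at the grid minimum", {
  # shallow divergence: the two-locus stand-in assumes infinite sites,
  # so homoplasy (recurrent mutation) must stay negligible
  tr <- ape::read.tree(
    text = "((a:0.02,b:0.02):0.02,(c:0.02,d:0.02):0.02,(e:0.02,f:0.02):0.02);")
  rhos <- vapply(1:9, function(sd) {
    ev <- evolve_codon_sequences(tr, 150, omega = 1, seed = 300 + sd)
    estimate_rho_theta(alignment(ev$leaf, kind = "nucleotide"))$rho
  }, numeric(1))
  expect_equal(stats::median(rhos), 0)
})
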