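test_that("strand consensus: identity, mismatch, IUPAC compatibility", {
  s <- random_codon_seq(20, seed = 1)
  ok <- build_consensus(s, crocmhc:::revcomp(s))
  expect_equal(ok$seq, s)
  expect_null(ok$rejection)

  bad <- s
  substr(bad, 10, 10) <- if (substr(s, 10, 10) == "A") "C" else "A"
  res <- build_consensus(s, crocmhc:::revcomp(bad))
  expect_null(res$seq)
  expect_equal(res$rejection$rule, "strand_mismatch")

  # 'R' (A/G) against 'A' is compatible and resolves to 'A'
  fwd <- s; substr(fwd, 5, 5) <- "R"
  rev <- s; substr(rev, 5, 5) <- "A"
  res2 <- build_consensus(fwd, crocmhc:::revcomp(rev))
  expect_equal(substr(res2$seq, 5, 5), "A")

  expect_error(build_consensus(s, "ACGT"), "overlap")
})

test_that("support screening implements the two-route acceptance rule", {
  v1 <- random_codon_seq(20, seed = 2)
  v2 <- random_codon_seq(20, seed = 3)
  v3 <- random_codon_seq(20, seed = 4)
  cons <- data.frame(
    clone_id = paste0("c", 1:6),
    species = c("Crpo", "Crpo", "Crpo", "Crpo", "Cacr", "Crpo"),
    individual_id = c("i1", "i1", "i1", "i2", "i3", "i1"),
    pcr_id = c("p1", "p1", "p1", "p2", "p3", "p1"),
    exon_target = "IIb_ex3",
    seq = c(v1, v1, v1, v2, v2, v3),
    stringsAsFactors = FALSE)
  res <- collapse_and_screen(cons)
  cand <- res$candidates
  # v1: 3 clones in one individual
  expect_equal(cand$n_clones[cand$seq == v1], 3L)
  # v2: one clone each in two individuals of two species -> accepted twice
  expect_setequal(cand$species[cand$seq == v2], c("Crpo", "Cacr"))
  expect_true(all(cand$n_individuals[cand$seq == v2] == 2L))
  # v3: singleton
  expect_equal(res$rejections$seq, v3)
  expect_equal(res$rejections$rule, "singleton_unsupported")
})

test_that("near-redundancy rule: <3 bp from a redundant sequence", {
  base <- random_codon_seq(30, seed = 5)
  flip <- function(s, p) {
    substr(s, p, p) <- setdiff(c("A", "C"), substr(s, p, p))[1]
    s
  }
  near2 <- flip(flip(base, 4), 8)
  exact3 <- base
  for (p in c(12, 16, 20))
    substr(exact3, p, p) <- setdiff(c("A", "C"),
                                    substr(base, p, p))[1]
  stopifnot(crocmhc:::seq_distance_bp(base, near2) == 2,
            crocmhc:::seq_distance_bp(base, exact3) == 3)
  cons <- data.frame(
    clone_id = paste0("c", 1:6),
    species = "Crpo", individual_id = "i1", pcr_id = "p1",
    exon_target = "IIb_ex3",
    seq = c(base, base, base, base, near2, exact3),
    stringsAsFactors = FALSE)
  rej <- filter_near_redundant(cons, exempt_rescued = FALSE)
  expect_equal(rej$seq, near2)           # 2 bp away: discarded
  expect_false(exact3 %in% rej$seq)      # exactly 3 bp: retained

  # two singletons 1 bp apart with no redundant partner: neither removed
  a <- random_codon_seq(30, seed = 6)
  b <- a; substr(b, 2, 2) <- setdiff(c("A", "G"), substr(a, 2, 2))[1]
  cons2 <- data.frame(clone_id = c("c1", "c2"), species = "Crpo",
                      individual_id = "i1", pcr_id = "p1",
                      exon_target = "IIb_ex3", seq = c(a, b),
                      stringsAsFactors = FALSE)
  expect_equal(nrow(filter_near_redundant(cons2, exempt_rescued = FALSE)),
               0L)
})

test_that("chimera detection: exact single-crossover composition", {
  v1 <- random_codon_seq(87, seed = 7)   # 261 nt
  v2 <- random_codon_seq(87, seed = 8)
  chim <- paste0(substr(v1, 1, 120), substr(v2, 121, 261))
  flags <- detect_within_individual_chimeras(
    c(a = v1, b = v2, c = chim))
  expect_equal(flags$name, "c")
  expect_setequal(c(flags$parent1, flags$parent2), c("a", "b"))
  expect_true(flags$k_min <= 120 && 120 <= flags$k_max)

  # two variants: no flags possible
  expect_equal(nrow(detect_within_individual_chimeras(
    c(a = v1, b = v2))), 0L)

  # random triples without exact composition: agree with brute force
  set.seed(42)
  for (r in 1:20) {
    trio <- c(a = random_codon_seq(20), b = random_codon_seq(20),
              c = random_codon_seq(20))
    got <- nrow(detect_within_individual_chimeras(trio)) > 0
    want <- any(vapply(1:3, function(i)
      oracle_is_chimera(trio[[i]], trio[-i]), logical(1)))
    expect_equal(got, want)
  }
})

test_that("naming is canonical and order-independent", {
  tax <- toy_taxonomy()
  cand <- data.frame(
    species = c("Crpo", "Crpo", "Cacr"),
    seq = c("ACGACG", "AAAAAA", "CCCCCC"),
    n_clones = c(5L, 2L, 3L), stringsAsFactors = FALSE)
  named <- assign_names(cand, tax, chain = "DB")
  expect_equal(named$name[named$seq == "ACGACG"], "Crpo-DB01")
  expect_equal(named$name[named$seq == "AAAAAA"], "Crpo-DB02")
  expect_equal(named$name[named$seq == "CCCCCC"], "Cacr-DB01")
  expect_true(all(grepl("^[A-Z][a-z]{3}-D[AB]\\d{2}$", named$name)))
  # permuted input gives the same assignment
  named2 <- assign_names(cand[c(3, 1, 2), ], tax, chain = "DB")
  expect_equal(named2[order(named2$name), "seq"],
               named[order(named$name), "seq"])
  # empty set and duplicates
  expect_equal(nrow(assign_names(cand[0, ], tax, "DB")), 0L)
  dup <- rbind(cand, cand[1, ])
  expect_error(assign_names(dup, tax, "DB"), "duplicate")
})

test_that("validation partitions inputs and is order-independent", {
  sim <- simulate_dataset(test_sim_config(
    taxonomy = read_taxonomy()[c(1:3, 14:16), ]), seed = 21)
  tax <- read_taxonomy()
  val <- validate_clones(sim$reads, tax)
  # partition: every strand-consistent clone sequence is either a
  # validated variant's sequence or appears in exactly one rejection
  cons_seqs <- unique(val$consensus$seq)
  fate <- cons_seqs %in% val$variants$seq |
    cons_seqs %in% val$rejections$seq
  expect_true(all(fate))
  expect_false(any(duplicated(val$rejections[, c("seq", "rule")])))

  set.seed(9)
  shuffled <- sim$reads[sample(nrow(sim$reads)), ]
  class(shuffled) <- c("croc_reads", "data.frame")
  val2 <- validate_clones(shuffled, tax)
  expect_equal(val2$variants[order(val2$variants$name), c("name", "seq")],
               val$variants[order(val$variants$name), c("name", "seq")],
               ignore_attr = TRUE)
})

test_that("zero-noise simulation gives perfect recall with >=2 clones", {
  cfg <- test_sim_config(pcr_error_rate = 0, chimera_rate = 0,
                         clones_per_individual = c(8L, 8L),
                         within_species_alleles = 1L)
  sim <- simulate_dataset(cfg, seed = 31)
  val <- validate_clones(sim$reads, read_taxonomy())
  truth <- sim$truth
  clone_support <- table(truth$clones$source_allele)
  recoverable <- unique(truth$variants$seq[
    truth$variants$allele_id %in%
      names(clone_support)[clone_support >= 2]])
  expect_true(all(recoverable %in% val$variants$seq))
})
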