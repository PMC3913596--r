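test_that("translation follows the standard code with phase offsets", {
  expect_equal(translate_exon("ATGAAA"), "MK")
  expect_equal(translate_exon("TTAA", phase = 1), "*")
  expect_error(translate_exon(""), "empty")
  # length formula on random sequences
  set.seed(11)
  for (phase in 0:2) {
    nt <- paste(sample(c("A", "C", "G", "T"), 171, replace = TRUE),
                collapse = "")
    expect_equal(nchar(translate_exon(nt, phase)),
                 (171 - phase) %/% 3)
  }
  # ambiguity and gaps render as X
  expect_equal(translate_exon("ARG"), "X")
  expect_equal(translate_exon("A-G"), "X")
})

test_that("frameshift detection locates non-triplet gaps", {
  ref <- random_codon_seq(40, seed = 12)
  # delete 1 nt inside codon 12 (nt positions 34-36)
  mut <- paste0(substr(ref, 1, 34), substr(ref, 36, nchar(ref)))
  ev <- detect_frameshift(mut, ref)
  fs <- ev[ev$frameshift, ]
  expect_equal(nrow(fs), 1L)
  expect_equal(fs$aa_site, 12L)
  expect_equal(fs$length, 1L)

  # in-frame 3-nt deletion: reported but not frameshifting
  mut3 <- paste0(substr(ref, 1, 33), substr(ref, 37, nchar(ref)))
  ev3 <- detect_frameshift(mut3, ref)
  expect_true(all(!ev3$frameshift))

  expect_equal(nrow(detect_frameshift(ref, ref)), 0L)
  expect_error(detect_frameshift(ref, NULL), "reference")
})

test_that("functionality classification enumerates all triggers", {
  aa_ok <- paste(rep("A", 86), collapse = "")
  spec <- conserved_site_spec("IIb_ex3")
  # intact ORF with required cysteines present
  good <- aa_ok
  substr(good, 24, 24) <- "C"; substr(good, 80, 80) <- "C"
  call <- classify_functionality(good, NULL, spec)
  expect_equal(call$class, "functional")
  expect_length(call$reasons, 0L)
  # stop at aa 31
  stopped <- good; substr(stopped, 31, 31) <- "*"
  call2 <- classify_functionality(stopped, NULL, spec)
  expect_equal(call2$class, "non_functional")
  expect_equal(call2$reasons, "stop_codon@31")
  # cysteine 24 mutated
  nocys <- good; substr(nocys, 24, 24) <- "S"
  call3 <- classify_functionality(nocys, NULL, spec)
  expect_equal(call3$reasons, "missing_conserved@24")
  # classification is deterministic/idempotent
  expect_identical(classify_functionality(nocys, NULL, spec), call3)
})

test_that("planted pseudogene lesions are recovered on true variants", {
  cfg <- test_sim_config(pseudogene_rate = 0.6, pcr_error_rate = 0,
                         chimera_rate = 0)
  sim <- simulate_dataset(cfg, seed = 41)
  truth <- sim$truth
  expect_gt(nrow(truth$pseudogenes), 0L)
  tv <- unique(truth$variants[, c("allele_id", "exon_target", "seq")])
  tv$name <- tv$allele_id
  ann <- annotate_variants(tv, check_conserved = FALSE)
  lesioned <- truth$pseudogenes$allele_id
  seen <- ann$name %in% lesioned
  expect_true(all(ann$functionality[seen] == "non_functional"))
  # un-lesioned alleles stay functional (stop/frameshift checks only)
  expect_true(all(ann$functionality[!seen] == "functional"))
})

test_that("shipped conserved-site specs are coherent", {
  for (tg in c("IIa_ex2", "IIa_ex3", "IIb_ex3")) {
    sp <- conserved_site_spec(tg)
    expect_true(sp$phase %in% 0:2)
  }
  expect_equal(conserved_site_spec("IIb_ex3")$cys_pair, c(24L, 80L))
  expect_error(conserved_site_spec("nope"), "no conserved-site spec")
})
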