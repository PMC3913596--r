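test_that("distance matrix matches closed forms", {
  s <- random_codon_seq(400, seed = 17)  # 1200 nt
  # plant exactly 30% differences
  v <- strsplit(s, "")[[1]]
  set.seed(18)
  idx <- sample(length(v), 360)
  w <- v
  for (i in idx) w[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  aln <- alignment(c(a = s, b = paste(w, collapse = "")))
  D <- distance_matrix(aln, substitution_model("JC69"))
  p <- 360 / 1200
  expect_equal(D["a", "b"], -3 / 4 * log(1 - 4 * p / 3),
               tolerance = 1e-9)
  expect_equal(D["a", "a"], 0)
  # gamma correction never shrinks a distance
  Dg <- distance_matrix(aln, substitution_model("JC69",
                                                gamma_alpha = 0.5))
  expect_gte(Dg["a", "b"], D["a", "b"])
})

test_that("NJ recovers additive matrices exactly", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):1);")
  D <- ape::cophenetic.phylo(tr)
  res <- nj_tree(D)
  expect_s3_class(res$tree, "phylo")
  expect_equal(ape::dist.topo(ape::unroot(tr), res$tree), 0,
               ignore_attr = TRUE)
  expect_equal(ape::cophenetic.phylo(res$tree)[rownames(D), colnames(D)],
               D, tolerance = 1e-8)
  # 3 taxa: the unique unrooted tree
  res3 <- nj_tree(D[1:3, 1:3])
  expect_equal(sort(res3$tree$tip.label), c("A", "B", "C"))
  # permutation invariance of the topology
  perm <- c("C", "A", "D", "B")
  res_p <- nj_tree(D[perm, perm])
  expect_equal(ape::dist.topo(res$tree, res_p$tree), 0,
               ignore_attr = TRUE)
  Dna <- D; Dna[1, 2] <- Dna[2, 1] <- NA
  expect_error(nj_tree(Dna), "missing")
})

test_that("pruning likelihood matches the closed-form 2-taxon case", {
  s1 <- random_codon_seq(100, seed = 19)
  s2 <- random_codon_seq(100, seed = 20)
  aln <- alignment(c(a = s1, b = s2))
  t <- 0.2
  tree <- ape::read.tree(text = sprintf("(a:%f,b:%f);", t / 2, t / 2))
  model <- substitution_model("JC69")
  ll <- sum(phylo_site_loglik(tree, aln, model))
  # JC69 closed form: P(same) and P(diff) for total divergence t
  p_same <- 1 / 4 + 3 / 4 * exp(-4 * t / 3)
  p_diff <- 1 / 4 - 1 / 4 * exp(-4 * t / 3)
  m <- do.call(rbind, strsplit(c(s1, s2), ""))
  nd <- sum(m[1, ] != m[2, ]); ns <- ncol(m) - nd
  expect_equal(ll, ns * (log(1 / 4) + log(p_same)) +
                 nd * (log(1 / 4) + log(p_diff)), tolerance = 1e-8)
})

test_that("model selection prefers parsimony on no-signal data and
           detects transition bias", {
  s <- random_codon_seq(120, seed = 21)
  ident <- alignment(stats::setNames(rep(s, 4), paste0("s", 1:4)))
  ms <- model_select(ident, gamma = FALSE)
  expect_equal(ms$best$name, "JC69")
  # K80-simulated data: K80 or richer beats JC69 by BIC
  tr <- ape::read.tree(
    text = "((a:0.15,b:0.15):0.05,(c:0.15,d:0.15):0.05);")
  ev <- evolve_codon_sequences(tr, 340, omega = 1, kappa = 8, seed = 22)
  aln <- alignment(ev$leaf)
  ms2 <- model_select(aln, gamma = FALSE)
  tab <- ms2$table
  expect_lt(min(tab$BIC[tab$model != "JC69"]),
            tab$BIC[tab$model == "JC69"])
  expect_true(ms2$best$name != "JC69")
})

test_that("bootstrap gives full support to a clean split and is
           reproducible", {
  a <- random_codon_seq(80, seed = 23)
  b <- strsplit(a, "")[[1]]
  set.seed(24)
  idx <- sample(length(b), 60)
  for (i in idx) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1)
  b <- paste(b, collapse = "")
  mut1 <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    for (i in k) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
    paste(v, collapse = "")
  }
  set.seed(25)
  aln <- alignment(c(a1 = a, a2 = mut1(a, 1:3), b1 = b,
                     b2 = mut1(b, 4:6)))
  bs <- bootstrap_support(aln, substitution_model("JC69"), reps = 100,
                          seed = 3)
  expect_equal(nrow(bs$support), 1L)
  expect_gt(bs$support$percent, 95)
  bs2 <- bootstrap_support(aln, substitution_model("JC69"), reps = 100,
                           seed = 3)
  expect_identical(bs$support, bs2$support)
})

test_that("ELW weights: symmetry, normalisation, signal", {
  tr_true <- ape::read.tree(
    text = "((a:0.1,b:0.1):0.15,(c:0.1,d:0.1):0.15);")
  ev <- evolve_codon_sequences(tr_true, 400, omega = 1, seed = 26)
  aln <- alignment(ev$leaf)
  model <- substitution_model("JC69")
  # identical trees split the weight evenly
  w_same <- elw_compare(aln, model, tr_true, tr_true, rell_reps = 300,
                        seed = 4)
  expect_equal(w_same$weight, c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(sum(w_same$weight), 1)
  # the generating topology wins against a wrong one
  tr_wrong <- ape::read.tree(
    text = "((a:0.1,c:0.1):0.15,(b:0.1,d:0.1):0.15);")
  w <- elw_compare(aln, model, tr_true, tr_wrong, rell_reps = 300,
                   seed = 5)
  expect_gt(w$weight[1], 0.95)
  expect_equal(sum(w$weight), 1)
  expect_true(w$in_conf_set_95[1])
  tr_bad <- ape::read.tree(text = "((a:1,e:1):1,(b:1,c:1):1);")
  expect_error(elw_compare(aln, model, tr_true, tr_bad), "leaf sets")
})

test_that("diagnostic fixed differences between clades", {
  base <- strsplit(random_codon_seq(40, seed = 27), "")[[1]]
  mk <- function(subs) {
    v <- base
    for (p in names(subs)) v[as.integer(p)] <- subs[[p]]
    paste(v, collapse = "")
  }
  planted <- c(10L, 25L, 60L, 100L)
  c1_sub <- stats::setNames(rep("A", 4), planted)
  c2_sub <- stats::setNames(rep("G", 4), planted)
  base[planted] <- "C"
  aln <- alignment(c(x1 = mk(c1_sub), x2 = mk(c1_sub),
                     y1 = mk(c2_sub), y2 = mk(c2_sub)))
  clades <- c(x1 = "C1", x2 = "C1", y1 = "C2", y2 = "C2")
  sites <- diagnostic_fixed_differences(aln, clades)
  expect_equal(sites, planted, ignore_attr = TRUE)
  # identical content: no diagnostic sites
  aln0 <- alignment(c(x1 = mk(c1_sub), y1 = mk(c1_sub)))
  expect_length(diagnostic_fixed_differences(
    aln0, c(x1 = "C1", y1 = "C2")), 0L)
  expect_error(diagnostic_fixed_differences(aln, clades[1:3]),
               "no clade assignment")
})
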