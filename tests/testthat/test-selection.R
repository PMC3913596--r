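# shorter chains than the shipped defaults keep the suite fast; the
# acceptance tests exercise the criterion-level settings
fast_settings <- function(seed = 1L)
  mcmc_settings(iterations = 6000, burn_in = 1000, thinning = 5,
                seed = seed)

test_that("settings constructor validates burn-in", {
  expect_error(mcmc_settings(iterations = 100, burn_in = 100), "burn_in")
  s <- mcmc_settings()
  expect_equal(s$iterations, 5e5)
  expect_equal(s$burn_in, 5e4)
  expect_equal(s$n_orderings, 10)
  expect_equal(s$omega_model, "independent")
})

test_that("no-information limit: posterior close to prior", {
  s <- random_codon_seq(20, seed = 13)
  aln <- alignment(stats::setNames(rep(s, 5), paste0("s", 1:5)),
                   kind = "codon")
  scan <- site_omega_mcmc(aln, fast_settings(2))
  # log-uniform prior on [0.01, 100] puts mass 0.5 above 1; the composite
  # likelihood leaves a weak pull at zero counts, hence the loose band
  expect_true(all(abs(scan$sites$pp_positive - 0.5) < 0.25))
  expect_error(site_omega_mcmc(
    alignment(c(a = s, b = s), kind = "codon")), "at least 3")
})

test_that("pp_positive equals the fraction of retained samples above 1", {
  tr <- ape::read.tree(text = "((a:0.1,b:0.1):0.1,(c:0.1,d:0.1):0.1);")
  ev <- evolve_codon_sequences(tr, 20, omega = 0.5, seed = 3)
  aln <- alignment(ev$leaf, kind = "codon")
  scan <- site_omega_mcmc(aln, fast_settings(3))
  expect_equal(scan$sites$pp_positive,
               unname(colMeans(scan$samples > 1)))
  # HPD bounds bracket the mean and are ordered
  expect_true(all(scan$sites$hpd_low <= scan$sites$hpd_high))
  expect_true(all(scan$sites$omega_mean >= scan$sites$hpd_low - 1e-9))
})

test_that("PBR annotation applies the two-column neighbourhood rule", {
  tr <- ape::read.tree(text = "((a:0.1,b:0.1):0.1,(c:0.1,d:0.1):0.1);")
  ev <- evolve_codon_sequences(tr, 15, omega = 0.5, seed = 4)
  scan <- site_omega_mcmc(alignment(ev$leaf, kind = "codon"),
                          fast_settings(4), pbr_sites = c(5L, 12L))
  expect_true(scan$sites$is_pbr[5] && scan$sites$is_pbr[12])
  expect_true(scan$sites$is_pbr[7])    # distance 2
  expect_false(scan$sites$is_pbr[9])   # distance 3 from both
  expect_equal(scan$sites$pbr_distance[1], 4L)
})

test_that("site classification uses strict thresholds", {
  sites <- data.frame(codon_site = 1:4,
                      pp_positive = c(0.90, 0.99, 0.995, 0.951))
  cls <- classify_selected_sites(sites)
  expect_equal(cls$class,
               c("none", "significant", "highly_significant",
                 "significant"))
})

test_that("codon Z-test: null, signal and error paths", {
  s <- random_codon_seq(30, seed = 14)
  null_aln <- alignment(stats::setNames(rep(s, 4), paste0("s", 1:4)),
                        kind = "codon")
  zt <- codon_z_test(null_aln, seed = 1)
  expect_equal(zt$statistic, 0)
  expect_equal(zt$p_value, 0.5)

  # strong diversifying signal: positive statistic, small p
  tr <- ape::read.tree(
    text = "((a:0.25,b:0.25):0.1,(c:0.25,d:0.25):0.1);")
  ev <- evolve_codon_sequences(tr, 60, omega = 8, seed = 5)
  sig <- codon_z_test(alignment(ev$leaf, kind = "codon"),
                      alternative = "dN>dS", seed = 2)
  expect_gt(sig$statistic, 0)
  expect_lt(sig$p_value, 0.05)
  # the opposite alternative on the same data is not significant
  opp <- codon_z_test(alignment(ev$leaf, kind = "codon"),
                      alternative = "dN<dS", seed = 2)
  expect_gt(opp$p_value, 0.5)

  # purifying signal supports dN<dS with a positive statistic
  ev2 <- evolve_codon_sequences(tr, 60, omega = 0.05, seed = 6)
  pur <- codon_z_test(alignment(ev2$leaf, kind = "codon"),
                      alternative = "dN<dS", seed = 3)
  expect_gt(pur$statistic, 0)
  expect_lt(pur$p_value, 0.05)

  expect_error(codon_z_test(null_aln, site_subset = integer(0)), "empty")
})

test_that("run comparison: identical seeds match, settings must agree", {
  tr <- ape::read.tree(text = "((a:0.1,b:0.1):0.1,(c:0.1,d:0.1):0.1);")
  ev <- evolve_codon_sequences(tr, 15, omega = 0.3, seed = 7)
  aln <- alignment(ev$leaf, kind = "codon")
  r1 <- site_omega_mcmc(aln, fast_settings(5))
  r1b <- site_omega_mcmc(aln, fast_settings(5))
  cmp <- compare_runs(r1, r1b, tolerance = 1e-9)
  expect_true(attr(cmp, "pass"))
  # two seeds: posterior probabilities agree tightly everywhere; means
  # agree on the informative sites (weakly informed sites wander more)
  r2 <- site_omega_mcmc(aln, fast_settings(6))
  cmp2 <- compare_runs(r1, r2, tolerance = 0.3)
  expect_true(all(cmp2$d_pp < 0.15))
  expect_gt(mean(cmp2$pass), 0.5)
  bad <- site_omega_mcmc(aln, mcmc_settings(iterations = 3000,
                                            burn_in = 500, thinning = 5,
                                            seed = 1))
  expect_error(compare_runs(r1, bad), "mismatched settings")
})
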