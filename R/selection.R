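# Site-wise Bayesian dN/dS (omega) estimation and codon-based Z-tests.
#
# The sampler targets the posterior of {mu, kappa, omega_site} under a
# composite NY98-style likelihood: per codon site, synonymous and
# nonsynonymous difference counts are accumulated over adjacent pairs of
# random sequence orderings (PAC flavour: each sequence is compared with
# its nearest predecessor in the ordering), and modelled as Poisson with
# rates mu*S_j(kappa) and mu*omega_j*N_j(kappa), where the site
# opportunities S_j/N_j are transition/transversion-weighted counts of
# non-stop single-nucleotide changes. This is a documented desk-scale
# simplification of a full phylogenetic codon likelihood; the omega model
# is independent across sites (no smoothing blocks).

# per-codon opportunity table: syn/nonsyn x ts/tv counts over the non-stop
# single-nucleotide neighbours
.codon_opp_env <- new.env(parent = emptyenv())

codon_opportunities <- function() {
  if (!is.null(.codon_opp_env$tab)) return(.codon_opp_env$tab)
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  is_ts <- function(a, b) (a %in% c("A", "G") && b %in% c("A", "G")) ||
    (a %in% c("C", "T") && b %in% c("C", "T"))
  tab <- matrix(0, nrow = length(gc), ncol = 4,
                dimnames = list(names(gc),
                                c("syn_ts", "syn_tv", "nonsyn_ts",
                                  "nonsyn_tv")))
  for (cd in names(gc)) {
    if (gc[[cd]] == "*") { tab[cd, ] <- NA_real_; next }
    for (pos in 1:3) {
      ref <- substr(cd, pos, pos)
      for (b in setdiff(bases, ref)) {
        alt <- cd; substr(alt, pos, pos) <- b
        if (gc[[alt]] == "*") next
        syn <- gc[[alt]] == gc[[cd]]
        ts <- is_ts(ref, b)
        col <- paste0(if (syn) "syn" else "nonsyn",
                      if (ts) "_ts" else "_tv")
        tab[cd, col] <- tab[cd, col] + 1
      }
    }
  }
  .codon_opp_env$tab <- tab
  tab
}

#' MCMC settings for the site-wise omega sampler
#'
#' Defaults mirror the analysis this package reimplements: 5e5 MCMC
#' iterations, 5e4 burn-in, thinning 100, codon frequencies 1/61, ten
#' random sequence orderings, independent omega model, two runs
#' recommended (see [compare_runs()]).
#'
#' @param iterations,burn_in,thinning chain control; \code{burn_in} must
#'   be smaller than \code{iterations}.
#' @param codon_frequency_model only \code{"1/61"} (uniform sense codons)
#'   is implemented.
#' @param n_orderings number of random sequence orderings averaged in the
#'   PAC-style count statistics.
#' @param omega_model only \code{"independent"} is implemented.
#' @param rho_model recombination is handled separately (see
#'   [estimate_rho_theta()]); kept for interface completeness.
#' @param seed integer seed.
#' @return list of class \code{mcmc_settings}.
#' @export
mcmc_settings <- function(iterations = 5e5, burn_in = 5e4, thinning = 100,
                          codon_frequency_model = "1/61",
                          n_orderings = 10, omega_model = "independent",
                          rho_model = "none", seed = 1L) {
  if (burn_in >= iterations) stop2("burn_in must be < iterations")
  structure(list(iterations = iterations, burn_in = burn_in,
                 thinning = thinning,
                 codon_frequency_model = codon_frequency_model,
                 n_orderings = n_orderings, omega_model = omega_model,
                 rho_model = rho_model, seed = as.integer(seed)),
            class = "mcmc_settings")
}

# accumulate per-site count/opportunity statistics over PAC orderings
pac_site_counts <- function(cm, n_orderings, seed) {
  n <- nrow(cm); C <- ncol(cm)
  opp <- codon_opportunities()
  scoreable <- matrix(codon_scoreable(cm), n, C)
  # nucleotide distance for nearest-predecessor choice
  nt <- do.call(rbind, strsplit(apply(cm, 1, paste, collapse = ""), ""))
  D <- matrix(0L, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    D[i, j] <- D[j, i] <- sum(nt[i, ] != nt[j, ])
  acc <- matrix(0, C, 6,
                dimnames = list(NULL, c("n", "s", "S_ts", "S_tv",
                                        "N_ts", "N_tv")))
  withr_seed <- function(expr) expr  # seeding handled by caller
  set.seed(seed)
  for (o in seq_len(n_orderings)) {
    ord <- sample.int(n)
    for (k in 2:n) {
      i <- ord[k]
      prev <- ord[seq_len(k - 1L)]
      j <- prev[which.min(D[i, prev])]
      ok <- scoreable[i, ] & scoreable[j, ]
      for (col in which(ok)) {
        c1 <- cm[i, col]; c2 <- cm[j, col]
        if (c1 != c2) {
          pc <- ng86_path_counts(c1, c2)
          acc[col, "n"] <- acc[col, "n"] + pc[["nd"]]
          acc[col, "s"] <- acc[col, "s"] + pc[["sd"]]
        }
        acc[col, 3:6] <- acc[col, 3:6] +
          (opp[c1, ] + opp[c2, ]) / 2
      }
    }
  }
  acc / n_orderings
}

hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  k <- max(1L, floor(prob * n))
  if (k >= n) return(c(lower = x[1], upper = x[n]))
  widths <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + k])
}

#' Site-wise Bayesian omega estimation
#'
#' Runs the composite-likelihood MCMC described in the package vignette
#' and returns per-codon-site posterior summaries: posterior mean omega,
#' 95% HPD bounds, and the posterior probability of diversifying
#' selection PP(omega > 1). Priors: log-uniform omega on [0.01, 100],
#' exponential(1) mu and kappa.
#'
#' @param aln codon \code{croc_alignment} with at least 3 sequences;
#'   unknown characters (gaps, ambiguity, stops) are treated as gaps.
#' @param settings [mcmc_settings()].
#' @param pbr_sites optional integer vector of peptide-binding-region
#'   codon columns used to annotate the output (\code{is_pbr} marks sites
#'   within \code{pbr_neighborhood} columns of a PBR site).
#' @param pbr_neighborhood neighbourhood radius in codon columns
#'   (default 2).
#' @return list of class \code{omega_scan}: \code{sites} data.frame
#'   (codon_site, omega_mean, hpd_low, hpd_high, pp_positive, is_pbr,
#'   pbr_distance), \code{samples} matrix of retained omega draws,
#'   \code{settings}, \code{acceptance} rates.
#' @export
site_omega_mcmc <- function(aln, settings = mcmc_settings(),
                            pbr_sites = NULL, pbr_neighborhood = 2L) {
  cm <- codon_matrix(aln)
  if (nrow(cm) < 3L) stop2("need at least 3 sequences")
  C <- ncol(cm)
  stats_seed <- derive_seed(settings$seed, "pac_orderings")
  acc <- pac_site_counts(cm, settings$n_orderings, stats_seed)
  n_j <- acc[, "n"]; s_j <- acc[, "s"]
  lw_lo <- log(0.01); lw_hi <- log(100)

  set.seed(derive_seed(settings$seed, "mcmc"))
  log_mu <- log(0.1); log_kappa <- 0
  log_w <- rep(0, C)
  site_ll <- function(log_w, log_mu, log_kappa) {
    kappa <- exp(log_kappa)
    S <- kappa * acc[, "S_ts"] + acc[, "S_tv"]
    N <- kappa * acc[, "N_ts"] + acc[, "N_tv"]
    lam_s <- exp(log_mu) * S
    lam_n <- exp(log_mu + log_w) * N
    s_j * log(pmax(lam_s, 1e-300)) - lam_s +
      n_j * log(pmax(lam_n, 1e-300)) - lam_n
  }
  cur_ll <- site_ll(log_w, log_mu, log_kappa)
  n_keep <- floor((settings$iterations - settings$burn_in) /
                    settings$thinning)
  samples <- matrix(NA_real_, n_keep, C)
  mu_samples <- numeric(n_keep); kappa_samples <- numeric(n_keep)
  kept <- 0L
  acc_w <- 0; acc_mu <- 0; acc_k <- 0
  for (it in seq_len(settings$iterations)) {
    # vectorised per-site RW on log omega (sites independent given mu,kappa)
    prop <- log_w + stats::rnorm(C, 0, 0.4)
    inside <- prop >= lw_lo & prop <= lw_hi
    prop_ll <- site_ll(prop, log_mu, log_kappa)
    accept <- inside & (log(stats::runif(C)) < prop_ll - cur_ll)
    log_w[accept] <- prop[accept]
    cur_ll[accept] <- prop_ll[accept]
    acc_w <- acc_w + mean(accept)
    # mu (exponential prior, log-RW with Jacobian)
    pm <- log_mu + stats::rnorm(1, 0, 0.15)
    pll <- site_ll(log_w, pm, log_kappa)
    lr <- sum(pll - cur_ll) + (exp(log_mu) - exp(pm)) + (pm - log_mu)
    if (log(stats::runif(1)) < lr) {
      log_mu <- pm; cur_ll <- pll; acc_mu <- acc_mu + 1
    }
    # kappa
    pk <- log_kappa + stats::rnorm(1, 0, 0.15)
    pll <- site_ll(log_w, log_mu, pk)
    lr <- sum(pll - cur_ll) + (exp(log_kappa) - exp(pk)) + (pk - log_kappa)
    if (log(stats::runif(1)) < lr) {
      log_kappa <- pk; cur_ll <- pll; acc_k <- acc_k + 1
    }
    if (it > settings$burn_in &&
        (it - settings$burn_in) %% settings$thinning == 0L) {
      kept <- kept + 1L
      samples[kept, ] <- exp(log_w)
      mu_samples[kept] <- exp(log_mu)
      kappa_samples[kept] <- exp(log_kappa)
    }
  }
  samples <- samples[seq_len(kept), , drop = FALSE]
  hpd <- apply(samples, 2, hpd_interval)
  sites <- data.frame(
    codon_site = seq_len(C),
    omega_mean = colMeans(samples),
    hpd_low = hpd["lower", ],
    hpd_high = hpd["upper", ],
    pp_positive = colMeans(samples > 1),
    n_diffs = n_j + s_j
  )
  if (!is.null(pbr_sites)) {
    dist <- vapply(sites$codon_site, function(i)
      min(abs(i - pbr_sites)), numeric(1))
    sites$pbr_distance <- as.integer(dist)
    sites$is_pbr <- dist <= pbr_neighborhood
  } else {
    sites$pbr_distance <- NA_integer_
    sites$is_pbr <- NA
  }
  structure(list(sites = sites, samples = samples,
                 mu = mu_samples, kappa = kappa_samples,
                 settings = settings,
                 acceptance = c(omega = acc_w / settings$iterations,
                                mu = acc_mu / settings$iterations,
                                kappa = acc_k / settings$iterations)),
            class = "omega_scan")
}

#' @export
print.omega_scan <- function(x, ...) {
  cat(sprintf("<omega_scan> %d codon sites, %d retained samples\n",
              nrow(x$sites), nrow(x$samples)))
  cat(sprintf("  sites with PP(omega>1) > 0.95: %d\n",
              sum(x$sites$pp_positive > 0.95)))
  invisible(x)
}

#' Classify sites by posterior probability of diversifying selection
#'
#' Labels each codon site \code{none}, \code{significant}
#' (PP strictly > \code{significant}) or \code{highly_significant}
#' (PP strictly > \code{highly_significant}).
#'
#' @param posteriors \code{omega_scan} or its \code{sites} data.frame.
#' @param significant,highly_significant strict thresholds (defaults
#'   0.95 and 0.99).
#' @return data.frame with \code{codon_site}, \code{pp_positive},
#'   \code{class}.
#' @export
classify_selected_sites <- function(posteriors, significant = 0.95,
                                    highly_significant = 0.99) {
  sites <- if (inherits(posteriors, "omega_scan")) posteriors$sites
           else posteriors
  pp <- sites$pp_positive
  cls <- rep("none", length(pp))
  cls[pp > significant] <- "significant"
  cls[pp > highly_significant] <- "highly_significant"
  data.frame(codon_site = sites$codon_site, pp_positive = pp,
             class = cls, stringsAsFactors = FALSE)
}

#' Codon-based Z-test of selection
#'
#' Tests H0: dN = dS against a one-sided alternative over all sequence
#' pairs, restricted to a codon-column subset (e.g. the PBR). The
#' statistic is (mean dN - mean dS) / SE (sign flipped for the dN < dS
#' alternative so that support for the alternative is positive); the SE
#' comes from bootstrap resampling of codon sites.
#'
#' @param aln codon \code{croc_alignment}.
#' @param site_subset integer codon columns (NULL = all).
#' @param alternative \code{"dN>dS"} or \code{"dN<dS"}.
#' @param bootstrap_reps bootstrap replicates for the SE (default 1000).
#' @param seed integer seed for the bootstrap.
#' @return list of class \code{codon_z_test}: \code{statistic},
#'   \code{p_value}, \code{alternative}, \code{mean_dN}, \code{mean_dS},
#'   \code{site_subset}, \code{bootstrap_reps}, \code{seed}.
#' @export
codon_z_test <- function(aln, site_subset = NULL,
                         alternative = c("dN>dS", "dN<dS"),
                         bootstrap_reps = 1000L, seed = 1L) {
  alternative <- match.arg(alternative)
  cm <- codon_matrix(aln)
  sites <- site_subset %||% seq_len(ncol(cm))
  if (length(sites) == 0L) stop2("site subset is empty")
  if (any(sites < 1L | sites > ncol(cm))) stop2("subset out of range")
  n <- nrow(cm)
  pairs <- utils::combn(n, 2L)
  # per-pair, per-column NG86 contributions, computed once so that the
  # site bootstrap reduces to matrix sums
  env <- ng86_tables()
  P <- ncol(pairs); C <- length(sites)
  ND <- SD <- NS <- SS <- matrix(0, P, C)
  for (p in seq_len(P)) {
    i <- pairs[1, p]; j <- pairs[2, p]
    for (k in seq_len(C)) {
      c1 <- cm[i, sites[k]]; c2 <- cm[j, sites[k]]
      if (!(codon_scoreable(c1) && codon_scoreable(c2))) {
        NS[p, k] <- NA
        next
      }
      s_sites <- (env$sites[[c1]] + env$sites[[c2]]) / 2
      SS[p, k] <- s_sites
      NS[p, k] <- 3 - s_sites
      if (c1 != c2) {
        pc <- ng86_path_counts(c1, c2)
        ND[p, k] <- pc[["nd"]]; SD[p, k] <- pc[["sd"]]
      }
    }
  }
  stat_fun <- function(cols) {
    usable <- !is.na(NS[, cols, drop = FALSE])
    Ns <- rowSums(NS[, cols, drop = FALSE], na.rm = TRUE)
    Ss <- rowSums(SS[, cols, drop = FALSE], na.rm = TRUE)
    pN <- rowSums(ND[, cols, drop = FALSE] * usable, na.rm = TRUE) / Ns
    pS <- rowSums(SD[, cols, drop = FALSE] * usable, na.rm = TRUE) / Ss
    mean(jc_correct(pN) - jc_correct(pS), na.rm = TRUE)
  }
  cols0 <- seq_len(C)
  obs <- stat_fun(cols0)
  if (is.na(obs)) stop2("no countable sites in subset")
  test_ng <- nei_gojobori(aln, subset = sites)
  set.seed(seed)
  boot <- vapply(seq_len(bootstrap_reps), function(r)
    stat_fun(sample(cols0, C, replace = TRUE)), numeric(1))
  se <- stats::sd(boot, na.rm = TRUE)
  signed <- if (alternative == "dN>dS") obs else -obs
  z <- if (!is.finite(se) || se == 0) {
    if (isTRUE(all.equal(signed, 0)) || signed == 0) 0 else sign(signed) * Inf
  } else signed / se
  p <- stats::pnorm(z, lower.tail = FALSE)
  m <- attr(test_ng, "means")
  structure(list(statistic = z, p_value = p, alternative = alternative,
                 mean_dN = m[["dN"]], mean_dS = m[["dS"]],
                 site_subset = sites, variance_method = "bootstrap",
                 bootstrap_reps = bootstrap_reps, seed = seed),
            class = "codon_z_test")
}

#' @export
print.codon_z_test <- function(x, ...) {
  cat(sprintf("Codon Z-test, H_A: %s\n", x$alternative))
  cat(sprintf("  Test statistic = %.3f; P-value = %.3f\n",
              x$statistic, x$p_value))
  invisible(x)
}

#' Compare two MCMC runs for convergence
#'
#' Two independent runs (identical settings except the seed) agree when
#' per-site differences in posterior mean omega and PP(omega > 1) are all
#' below the tolerance; only results that match within an acceptable
#' degree of error should be interpreted.
#'
#' @param run1,run2 \code{omega_scan} objects.
#' @param tolerance per-site tolerance on |delta omega_mean| and
#'   |delta pp_positive|.
#' @return data.frame of per-site deltas with attribute \code{pass}.
#' @export
compare_runs <- function(run1, run2, tolerance = 0.1) {
  s1 <- run1$settings; s2 <- run2$settings
  same <- vapply(setdiff(names(s1), "seed"), function(f)
    identical(s1[[f]], s2[[f]]), logical(1))
  if (!all(same))
    stop2("runs have mismatched settings: ",
          paste(names(same)[!same], collapse = ", "))
  if (nrow(run1$sites) != nrow(run2$sites))
    stop2("runs cover different numbers of sites")
  d <- data.frame(
    codon_site = run1$sites$codon_site,
    d_omega = abs(run1$sites$omega_mean - run2$sites$omega_mean),
    d_pp = abs(run1$sites$pp_positive - run2$sites$pp_positive)
  )
  d$pass <- d$d_omega < tolerance & d$d_pp < tolerance
  attr(d, "pass") <- all(d$pass)
  d
}
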