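# Distance phylogenetics: nucleotide substitution models (JC69, K80,
# HKY85, TN93) with discrete-gamma rate heterogeneity, Felsenstein
# pruning likelihood, model selection by BIC/AIC, deterministic neighbor
# joining, nonparametric bootstrap supports, RELL-based expected
# likelihood weights, and clade diagnostic sites.

#' Construct a substitution model
#'
#' @param name one of \code{JC69}, \code{K80}, \code{HKY85}, \code{TN93}.
#' @param kappa transition/transversion rate ratio (K80, HKY85).
#' @param alpha1,alpha2 purine and pyrimidine transition rates relative
#'   to the transversion rate (TN93).
#' @param base_frequencies length-4 vector (A, C, G, T) summing to 1.
#' @param gamma_alpha shape of the gamma rate-heterogeneity distribution;
#'   \code{Inf} means uniform rates.
#' @param gamma_categories number of discrete gamma categories.
#' @return list of class \code{subst_model}.
#' @export
substitution_model <- function(name = c("JC69", "K80", "HKY85", "TN93"),
                               kappa = 2, alpha1 = 2, alpha2 = 2,
                               base_frequencies = rep(0.25, 4),
                               gamma_alpha = Inf, gamma_categories = 4L) {
  name <- match.arg(name)
  if (name %in% c("JC69", "K80"))
    base_frequencies <- rep(0.25, 4)
  if (abs(sum(base_frequencies) - 1) > 1e-8)
    stop2("base frequencies must sum to 1")
  if (!is.infinite(gamma_alpha) && gamma_alpha <= 0)
    stop2("gamma_alpha must be > 0")
  if (name == "JC69") { kappa <- 1; alpha1 <- 1; alpha2 <- 1 }
  if (name %in% c("K80", "HKY85")) { alpha1 <- kappa; alpha2 <- kappa }
  structure(list(name = name, kappa = kappa, alpha1 = alpha1,
                 alpha2 = alpha2,
                 base_frequencies = stats::setNames(base_frequencies,
                                                    c("A", "C", "G", "T")),
                 gamma_alpha = gamma_alpha,
                 gamma_categories = as.integer(gamma_categories)),
            class = "subst_model")
}

# normalized TN93-family rate matrix (rows/cols A, C, G, T)
model_Q <- function(model) {
  pi <- model$base_frequencies
  a1 <- model$alpha1; a2 <- model$alpha2
  Q <- matrix(0, 4, 4, dimnames = list(names(pi), names(pi)))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    b <- names(pi)[c(i, j)]
    rate <- if (all(b %in% c("A", "G"))) a1
            else if (all(b %in% c("C", "T"))) a2 else 1
    Q[i, j] <- rate * pi[j]
  }
  diag(Q) <- -rowSums(Q)
  Q / sum(-diag(Q) * pi)  # mean rate 1
}

# eigen decomposition of a reversible Q for fast P(t)
model_eigen <- function(model) {
  pi <- model$base_frequencies
  Q <- model_Q(model)
  D <- diag(sqrt(pi)); Di <- diag(1 / sqrt(pi))
  S <- D %*% Q %*% Di
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  list(U = Di %*% e$vectors, Uinv = t(e$vectors) %*% D,
       values = e$values)
}

p_matrix <- function(eig, t) {
  eig$U %*% diag(exp(eig$values * t)) %*% eig$Uinv
}

# mean rates of equal-probability discrete gamma categories
gamma_category_rates <- function(alpha, k = 4L) {
  if (is.infinite(alpha)) return(1)
  q <- stats::qgamma(seq(0, 1, length.out = k + 1L), alpha, alpha)
  p_up <- stats::pgamma(q[-1], alpha + 1, alpha)
  p_lo <- stats::pgamma(q[-(k + 1L)], alpha + 1, alpha)
  k * (p_up - p_lo)
}

# 4 x ncol likelihood indicators for a sequence (IUPAC aware; gap = 1,1,1,1)
tip_partials <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  sets <- iupac_bases(chars)
  out <- matrix(0, 4, length(chars), dimnames = list(c("A", "C", "G", "T"),
                                                     NULL))
  for (i in seq_along(sets)) {
    s <- sets[[i]]
    if (length(s) == 0L) out[, i] <- 1 else out[s, i] <- 1
  }
  out
}

#' Per-site log-likelihoods by Felsenstein pruning
#'
#' @param tree rooted or unrooted \code{ape::phylo} with branch lengths.
#' @param aln nucleotide \code{croc_alignment} whose names cover the tip
#'   labels.
#' @param model \code{subst_model}.
#' @return numeric vector: log-likelihood of each alignment column,
#'   averaged over gamma rate categories.
#' @export
phylo_site_loglik <- function(tree, aln, model) {
  if (is.null(tree$edge.length)) stop2("tree needs branch lengths")
  miss <- setdiff(tree$tip.label, names(aln$records))
  if (length(miss)) stop2("alignment lacks tips: ",
                          paste(miss, collapse = ", "))
  tree <- stats::reorder(tree, "postorder")
  eig <- model_eigen(model)
  rates <- gamma_category_rates(model$gamma_alpha,
                                model$gamma_categories)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  S <- aln$ncol
  tips <- lapply(tree$tip.label, function(l) tip_partials(aln$records[[l]]))
  pi <- model$base_frequencies
  site_lik <- matrix(0, length(rates), S)
  for (rc in seq_along(rates)) {
    partial <- vector("list", ntip + nnode)
    partial[seq_len(ntip)] <- tips
    scale_log <- numeric(S)
    for (k in seq_len(nrow(tree$edge))) {
      parent <- tree$edge[k, 1]; child <- tree$edge[k, 2]
      P <- p_matrix(eig, pmax(tree$edge.length[k], 0) * rates[rc])
      contrib <- P %*% partial[[child]]
      if (is.null(partial[[parent]])) partial[[parent]] <- contrib
      else partial[[parent]] <- partial[[parent]] * contrib
    }
    root <- tree$edge[nrow(tree$edge), 1]
    lik <- as.numeric(pi %*% partial[[root]])
    site_lik[rc, ] <- log(pmax(lik, 1e-300))
  }
  # average likelihood over categories in a numerically safe way
  mx <- apply(site_lik, 2, max)
  mx + log(colMeans(exp(sweep(site_lik, 2, mx))))
}

#' Select a substitution model by BIC/AIC
#'
#' Computes the pruning likelihood of each candidate on a fixed
#' neighbor-joining starting topology (JC69 distances), optimizing the
#' model's free parameters (kappa or the two transition rates, and the
#' gamma shape when \code{gamma = TRUE}) with empirical base frequencies
#' for HKY85/TN93. The best model is chosen by BIC; AIC is reported.
#'
#' @param aln nucleotide \code{croc_alignment}, >= 4 sequences.
#' @param candidates model names to compare.
#' @param gamma include a gamma shape parameter (default TRUE).
#' @return list of class \code{model_selection}: \code{best}
#'   (\code{subst_model}), \code{table} (logLik, k, AIC, BIC per model).
#' @export
model_select <- function(aln,
                         candidates = c("JC69", "K80", "HKY85", "TN93"),
                         gamma = TRUE) {
  if (length(aln$records) < 4L) stop2("need at least 4 sequences")
  D <- distance_matrix(aln, substitution_model("JC69"))
  if (anyNA(D)) D[is.na(D)] <- max(D, na.rm = TRUE) * 1.5
  tree <- nj_tree(D)$tree
  emp <- empirical_base_freqs(aln)
  nsites <- aln$ncol
  fit_one <- function(name) {
    freqs <- if (name %in% c("JC69", "K80")) rep(0.25, 4) else emp
    npar_model <- switch(name, JC69 = 0L, K80 = 1L, HKY85 = 1L + 3L,
                         TN93 = 2L + 3L)
    make <- function(par) {
      ga <- if (gamma) exp(par[length(par)]) else Inf
      switch(name,
        JC69 = substitution_model("JC69", gamma_alpha = ga),
        K80 = substitution_model("K80", kappa = exp(par[1]),
                                 gamma_alpha = ga),
        HKY85 = substitution_model("HKY85", kappa = exp(par[1]),
                                   base_frequencies = freqs,
                                   gamma_alpha = ga),
        TN93 = substitution_model("TN93", alpha1 = exp(par[1]),
                                  alpha2 = exp(par[2]),
                                  base_frequencies = freqs,
                                  gamma_alpha = ga))
    }
    n_free <- switch(name, JC69 = 0L, K80 = 1L, HKY85 = 1L, TN93 = 2L) +
      as.integer(gamma)
    nll <- function(par) -sum(phylo_site_loglik(tree, aln, make(par)))
    if (n_free == 0L) {
      ll <- -nll(numeric(0))
      par <- numeric(0)
    } else {
      start <- c(rep(log(2), n_free - as.integer(gamma)),
                 if (gamma) log(1))
      opt <- stats::optim(start, nll, method = if (n_free == 1L)
        "Brent" else "Nelder-Mead",
        lower = if (n_free == 1L) -5 else -Inf,
        upper = if (n_free == 1L) 5 else Inf)
      ll <- -opt$value; par <- opt$par
    }
    k <- npar_model + as.integer(gamma)
    list(model = make(par), logLik = ll, k = k,
         AIC = -2 * ll + 2 * k, BIC = -2 * ll + k * log(nsites))
  }
  fits <- lapply(candidates, fit_one)
  tab <- data.frame(
    model = candidates,
    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
    k = vapply(fits, `[[`, integer(1), "k"),
    AIC = vapply(fits, `[[`, numeric(1), "AIC"),
    BIC = vapply(fits, `[[`, numeric(1), "BIC"))
  best <- fits[[which.min(tab$BIC)]]$model
  structure(list(best = best, table = tab), class = "model_selection")
}

empirical_base_freqs <- function(aln) {
  chars <- unlist(strsplit(unname(aln$records), ""))
  tab <- table(factor(chars, levels = c("A", "C", "G", "T")))
  f <- as.numeric(tab) / sum(tab)
  if (any(f == 0)) f <- (as.numeric(tab) + 1) / (sum(tab) + 4)
  f
}

#' Model-corrected pairwise distances
#'
#' Closed-form distances via \code{ape::dist.dna}: JC69, K80 and TN93
#' directly; HKY85 approximated by the TN93 distance. Gamma correction is
#' applied when the model's \code{gamma_alpha} is finite. Saturated pairs
#' (logarithm of a non-positive quantity) come back as \code{NA} with a
#' warning.
#'
#' @param aln nucleotide \code{croc_alignment}.
#' @param model \code{subst_model}.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(aln, model = substitution_model("JC69")) {
  chars <- do.call(rbind, strsplit(tolower(unname(aln$records)), ""))
  rownames(chars) <- names(aln$records)
  bin <- ape::as.DNAbin(chars)
  ape_model <- switch(model$name, JC69 = "JC69", K80 = "K80",
                      HKY85 = "TN93", TN93 = "TN93")
  g <- if (is.infinite(model$gamma_alpha)) FALSE else model$gamma_alpha
  D <- as.matrix(ape::dist.dna(bin, model = ape_model, gamma = g,
                               pairwise.deletion = TRUE))
  if (any(!is.finite(D))) {
    warning("saturated pair(s): distance undefined, reported as NA")
    D[!is.finite(D)] <- NA_real_
  }
  D
}

#' Deterministic neighbor joining
#'
#' Standard Saitou-Nei neighbor joining with an explicit tie-break: on
#' equal Q values the pair with the lowest (row, column) index in the
#' current matrix is joined. Recovers the topology and branch lengths of
#' any additive distance matrix exactly.
#'
#' @param D complete symmetric distance matrix with row/column names.
#' @return list of class \code{tree_result}: \code{tree}
#'   (\code{ape::phylo}), \code{newick}, \code{support} (NULL),
#'   \code{model} (NULL).
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (anyNA(D)) stop2("distance matrix has missing values")
  n <- nrow(D)
  if (n < 3L) stop2("need at least 3 taxa")
  labels <- rownames(D) %||% paste0("t", seq_len(n))
  node <- labels  # newick fragment per active node
  active <- seq_len(n)
  d <- D
  while (length(active) > 3L) {
    m <- length(active)
    r <- rowSums(d)
    Q <- (m - 2) * d - outer(r, r, `+`)
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    vi <- 0.5 * d[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    vj <- d[i, j] - vi
    new_lab <- sprintf("(%s:%.10g,%s:%.10g)", node[i], vi, node[j], vj)
    dn <- 0.5 * (d[i, ] + d[j, ] - d[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dn[keep]),
                c(dn[keep], 0))
    node <- c(node[keep], new_lab)
    rownames(d2) <- colnames(d2) <- NULL
    d <- d2
    active <- seq_len(m - 1L)
  }
  if (length(active) == 3L) {
    va <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
    vb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
    vc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
    newick <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                      node[1], va, node[2], vb, node[3], vc)
  } else {
    # n == 2 cannot occur (guarded above); n == 3 handled; remaining: exactly
    # the three-node case
    stop2("internal error in NJ reduction")
  }
  tree <- ape::read.tree(text = newick)
  structure(list(tree = tree, newick = newick, support = NULL,
                 model = NULL), class = "tree_result")
}

# canonical split representation: for each internal edge, the tip-label
# set on the side not containing the reference tip, sorted and joined
tree_splits <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[1]
  post <- stats::reorder(tree, "postorder")
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  for (k in seq_len(nrow(post$edge))) {
    p <- post$edge[k, 1]; c <- post$edge[k, 2]
    below[[p]] <- c(below[[p]], below[[c]])
  }
  splits <- character(0)
  for (k in seq_len(nrow(post$edge))) {
    child <- post$edge[k, 2]
    if (child <= ntip) next  # trivial split
    side <- below[[child]]
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    if (length(side) < 2L || length(side) > ntip - 2L) next
    splits <- c(splits, paste(sort(side), collapse = "|"))
  }
  unique(splits)
}

#' Nonparametric bootstrap supports for a distance tree
#'
#' Builds the NJ tree from model-corrected distances, then resamples
#' alignment columns with replacement \code{reps} times; the support of
#' each internal edge is the percentage of replicates whose NJ tree
#' contains the same bipartition.
#'
#' @param aln nucleotide \code{croc_alignment}.
#' @param model \code{subst_model}.
#' @param reps bootstrap replicates (the field standard is 1e4; scale
#'   down for quick checks).
#' @param seed integer seed.
#' @return \code{tree_result} with \code{support}: data.frame
#'   \code{split}, \code{percent}.
#' @export
bootstrap_support <- function(aln, model = substitution_model("JC69"),
                              reps = 1e4, seed = 1L) {
  D <- distance_matrix(aln, model)
  if (anyNA(D)) stop2("saturated distances; choose another model")
  res <- nj_tree(D)
  orig_splits <- tree_splits(res$tree)
  counts <- stats::setNames(numeric(length(orig_splits)), orig_splits)
  used <- 0L
  m <- aln_matrix(aln)
  set.seed(seed)
  for (r in seq_len(reps)) {
    cols <- sample.int(ncol(m), replace = TRUE)
    rec <- apply(m[, cols, drop = FALSE], 1, paste, collapse = "")
    baln <- alignment(rec, kind = "nucleotide")
    Db <- tryCatch(distance_matrix(baln, model), warning = function(w) NULL,
                   error = function(e) NULL)
    if (is.null(Db) || anyNA(Db)) next
    bs <- tree_splits(nj_tree(Db)$tree)
    hit <- orig_splits %in% bs
    counts[hit] <- counts[hit] + 1
    used <- used + 1L
  }
  support <- data.frame(split = orig_splits,
                        percent = if (used > 0) 100 * counts / used
                                  else rep(NA_real_, length(orig_splits)))
  structure(list(tree = res$tree, newick = res$newick,
                 support = support, model = model, replicates_used = used),
            class = "tree_result")
}

#' Expected likelihood weights of two topologies (RELL)
#'
#' Computes per-site log-likelihoods of both trees under the model by
#' pruning, then resamples estimated log-likelihoods (RELL) to obtain
#' expected likelihood weights; reports whether each tree falls in the
#' 95% confidence tree set.
#'
#' @param aln nucleotide \code{croc_alignment}.
#' @param model \code{subst_model}.
#' @param tree_a,tree_b \code{ape::phylo} trees on the same leaf set,
#'   with branch lengths.
#' @param rell_reps RELL replicates (default 1e4).
#' @param seed integer seed.
#' @return data.frame: \code{tree}, \code{weight}, \code{in_conf_set_95}.
#' @export
elw_compare <- function(aln, model, tree_a, tree_b, rell_reps = 1e4,
                        seed = 1L) {
  if (!setequal(tree_a$tip.label, tree_b$tip.label))
    stop2("trees have different leaf sets")
  la <- phylo_site_loglik(tree_a, aln, model)
  lb <- phylo_site_loglik(tree_b, aln, model)
  S <- length(la)
  set.seed(seed)
  wa <- numeric(rell_reps)
  for (r in seq_len(rell_reps)) {
    idx <- sample.int(S, replace = TRUE)
    d <- sum(la[idx]) - sum(lb[idx])
    wa[r] <- 1 / (1 + exp(-d))
  }
  w <- c(a = mean(wa), b = 1 - mean(wa))
  ord <- order(w, decreasing = TRUE)
  cum <- cumsum(w[ord])
  in_set <- logical(2)
  in_set[ord] <- c(TRUE, cum[1] < 0.95)
  data.frame(tree = c("tree_a", "tree_b"), weight = as.numeric(w),
             in_conf_set_95 = in_set)
}

#' Diagnostic fixed differences between two clades
#'
#' Returns the 1-based alignment columns where the residue sets of the
#' two clades are disjoint (gaps excluded); such sites diagnose clade
#' membership.
#'
#' @param aln \code{croc_alignment} (nucleotide or amino acid).
#' @param clades named vector mapping every sequence name to one of two
#'   clade labels.
#' @return integer vector of column positions; attribute
#'   \code{singleton_clade} flags a clade with a single member.
#' @export
diagnostic_fixed_differences <- function(aln, clades) {
  miss <- setdiff(names(aln$records), names(clades))
  if (length(miss)) stop2("no clade assignment for: ",
                          paste(miss, collapse = ", "))
  lv <- unique(clades[names(aln$records)])
  if (length(lv) != 2L) stop2("exactly two clades required")
  m <- aln_matrix(aln)
  g1 <- which(clades[rownames(m)] == lv[1])
  g2 <- which(clades[rownames(m)] == lv[2])
  gap <- c("-", ".")
  sites <- integer(0)
  for (j in seq_len(ncol(m))) {
    s1 <- setdiff(unique(m[g1, j]), gap)
    s2 <- setdiff(unique(m[g2, j]), gap)
    if (length(s1) && length(s2) && length(intersect(s1, s2)) == 0L)
      sites <- c(sites, j)
  }
  attr(sites, "singleton_clade") <-
    length(g1) == 1L || length(g2) == 1L
  sites
}
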