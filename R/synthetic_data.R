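# Multigene-family amplicon simulator with full ground truth. The stated
# world: diploid individuals of 20 crocodylian species on a two-family
# species tree; one class II alpha locus and two beta loci; codon
# sequences evolved under an NY98-style model with site-specific omega
# (elevated at peptide-binding columns, zero at conserved columns);
# trans-species retention planted by copying ancestral alleles into
# descendant species; pseudogenizing stops/deletions; clones sampled with
# PCR point errors and single-crossover chimeras.

#' Simulation configuration
#'
#' Defaults mirror the study design this package models: amplicon
#' lengths 171/240/260 nt for the three exon targets, one alpha and two
#' beta loci, two individuals per species, four to six clones per
#' individual, PCR point-error rate 0.002/nt and chimera rate 0.1 per
#' clone. See the methods vignette for the rationale behind values the
#' source design leaves open (tree depth, retention and pseudogene
#' rates, within-species allele counts).
#'
#' @param targets named list of amplicon targets; each entry has
#'   \code{length} (nt), \code{loci}, \code{phase}.
#' @param taxonomy \code{croc_taxonomy} (default: shipped 20 species).
#' @param species_tree \code{ape::phylo} with branch lengths in expected
#'   substitutions per codon; default: deterministic two-family tree of
#'   depth \code{tree_depth}.
#' @param tree_depth root-to-tip depth of the default tree.
#' @param individuals_per_species,clones_per_individual sampling design
#'   (clone count drawn uniformly from the given range).
#' @param pcr_error_rate per-nucleotide PCR point-error probability.
#' @param chimera_rate per-clone probability of a single-crossover
#'   chimera.
#' @param retention_rate per internal node and locus, probability that
#'   the ancestral allele is retained identically in several descendant
#'   species (the trans-species polymorphism generator).
#' @param pseudogene_rate per species and locus, probability that one
#'   pool allele carries a pseudogenizing lesion (premature stop or 1-bp
#'   deletion, equally likely).
#' @param within_species_alleles alleles per species and locus pool.
#' @param kappa transition/transversion ratio of the codon model.
#' @param omega_background,omega_pbr site omega off/on the
#'   peptide-binding columns (exon 2 targets only).
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(targets = list(
                         IIa_ex2 = list(length = 171L, loci = 1L,
                                        phase = 0L),
                         IIa_ex3 = list(length = 240L, loci = 1L,
                                        phase = 0L),
                         IIb_ex3 = list(length = 260L, loci = 2L,
                                        phase = 2L)),
                       taxonomy = read_taxonomy(),
                       species_tree = NULL, tree_depth = 0.3,
                       individuals_per_species = 2L,
                       clones_per_individual = c(4L, 6L),
                       pcr_error_rate = 0.002, chimera_rate = 0.1,
                       retention_rate = 0.2, pseudogene_rate = 0.1,
                       within_species_alleles = 2L, kappa = 2,
                       omega_background = 0.2, omega_pbr = 4) {
  rates <- c(pcr_error_rate, chimera_rate, retention_rate,
             pseudogene_rate)
  if (any(rates < 0 | rates > 1)) stop2("rates must lie in [0, 1]")
  for (nm in names(targets)) {
    tg <- targets[[nm]]
    if ((tg$length - tg$phase) %/% 3L < 10L)
      stop2("target ", nm, " too short")
  }
  if (is.null(species_tree))
    species_tree <- default_species_tree(taxonomy, depth = tree_depth)
  structure(list(targets = targets, taxonomy = taxonomy,
                 species_tree = species_tree,
                 individuals_per_species = as.integer(individuals_per_species),
                 clones_per_individual = as.integer(clones_per_individual),
                 pcr_error_rate = pcr_error_rate,
                 chimera_rate = chimera_rate,
                 retention_rate = retention_rate,
                 pseudogene_rate = pseudogene_rate,
                 within_species_alleles = as.integer(within_species_alleles),
                 kappa = kappa, omega_background = omega_background,
                 omega_pbr = omega_pbr),
            class = "sim_config")
}

#' Deterministic two-family species tree
#'
#' Caterpillar topologies within each family, joined at the root, all
#' tips equidistant from the root (ultrametric), depth in expected
#' substitutions per codon.
#'
#' @param taxonomy \code{croc_taxonomy}.
#' @param depth root-to-tip length.
#' @return \code{ape::phylo}.
#' @export
default_species_tree <- function(taxonomy, depth = 0.3) {
  # ultrametric caterpillar of total tip depth `total`
  caterpillar <- function(tips, total) {
    k <- length(tips)
    if (k == 1L) return(sprintf("%s:%.8f", tips, total))
    ds <- total * seq_len(k - 1L) / (k - 1L)  # join depths, shallow first
    s <- sprintf("(%s:%.8f,%s:%.8f)", tips[1], ds[1], tips[2], ds[1])
    for (i in seq_len(k - 2L)) {
      s <- sprintf("(%s:%.8f,%s:%.8f)", s, ds[i + 1L] - ds[i],
                   tips[i + 2L], ds[i + 1L])
    }
    s
  }
  fams <- split(taxonomy$gene_prefix, taxonomy$family)
  fam_depth <- 0.7 * depth
  stem <- depth - fam_depth
  parts <- vapply(fams, function(tips) {
    if (length(tips) == 1L) sprintf("%s:%.8f", tips, depth)
    else sprintf("%s:%.8f", caterpillar(sort(tips), fam_depth), stem)
  }, character(1))
  txt <- sprintf("(%s,%s);", parts[1], parts[2])
  ape::read.tree(text = txt)
}

# 61 sense codons, neighbour lists and NY98 rate ingredients
.codon_sim_env <- new.env(parent = emptyenv())

codon_model_tables <- function() {
  if (!is.null(.codon_sim_env$tab)) return(.codon_sim_env$tab)
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  idx <- stats::setNames(seq_along(sense), sense)
  bases <- c("A", "C", "G", "T")
  nb <- vector("list", length(sense))
  for (i in seq_along(sense)) {
    cd <- sense[i]
    rows <- list()
    for (pos in 1:3) {
      ref <- substr(cd, pos, pos)
      for (b in setdiff(bases, ref)) {
        alt <- cd; substr(alt, pos, pos) <- b
        if (gc[[alt]] == "*") next
        rows[[length(rows) + 1L]] <- c(
          to = idx[[alt]],
          ts = as.integer((ref %in% c("A", "G") && b %in% c("A", "G")) ||
                            (ref %in% c("C", "T") && b %in% c("C", "T"))),
          nonsyn = as.integer(gc[[alt]] != gc[[cd]]))
      }
    }
    nb[[i]] <- do.call(rbind, rows)
  }
  tab <- list(sense = sense, idx = idx, neighbors = nb,
              aa = unname(gc[sense]))
  .codon_sim_env$tab <- tab
  tab
}

# total leaving rate for a site with given omega under uniform codon
# frequencies; the simulator normalizes by the MEAN over the omega
# profile, so branch lengths are expected substitutions per codon
# averaged across sites and high-omega sites evolve proportionally
# faster (standard codon-model scaling)
site_rate_scale <- function(omega, kappa) {
  tab <- codon_model_tables()
  tot <- vapply(tab$neighbors, function(nbm)
    sum(kappa^nbm[, "ts"] * omega^nbm[, "nonsyn"]), numeric(1))
  mean(tot)
}

#' Evolve codon sequences along a tree
#'
#' Continuous-time simulation per codon column under an NY98-style model
#' restricted to the 61 sense codons (uniform codon frequencies): the
#' rate of a single-nucleotide codon change is kappa^[transition] *
#' omega_site^[nonsynonymous], rescaled per site so that branch lengths
#' are expected substitutions per codon.
#'
#' @param tree \code{ape::phylo} with nonnegative branch lengths.
#' @param n_codons number of codon columns.
#' @param omega scalar or per-site vector of dN/dS values.
#' @param kappa transition/transversion ratio.
#' @param seed integer seed.
#' @param root_seq optional root codon string (length 3*n_codons).
#' @return list: \code{leaf} (named codon-sequence strings),
#'   \code{node} (internal-node sequences, named by node number),
#'   \code{omega} (per-site vector used).
#' @export
evolve_codon_sequences <- function(tree, n_codons, omega = 0.2,
                                   kappa = 2, seed = 1L,
                                   root_seq = NULL) {
  if (any(tree$edge.length < 0)) stop2("branch lengths must be >= 0")
  tab <- codon_model_tables()
  omega <- rep_len(omega, n_codons)
  set.seed(seed)
  root <- if (is.null(root_seq)) {
    sample.int(61L, n_codons, replace = TRUE)
  } else {
    cd <- codon_split(root_seq)
    if (length(cd) != n_codons) stop2("root_seq has wrong length")
    unname(tab$idx[cd])
  }
  scale <- rep(mean(vapply(omega, site_rate_scale, numeric(1),
                           kappa = kappa)), n_codons)
  ntip <- length(tree$tip.label)
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[ntip + 1L]] <- root
  pre <- stats::reorder(tree, "cladewise")
  for (k in seq_len(nrow(pre$edge))) {
    parent <- pre$edge[k, 1]; child <- pre$edge[k, 2]
    t_len <- pre$edge.length[k]
    s <- seqs[[parent]]
    for (j in seq_len(n_codons)) {
      t_rem <- t_len
      repeat {
        nbm <- tab$neighbors[[s[j]]]
        w <- kappa^nbm[, "ts"] * omega[j]^nbm[, "nonsyn"]
        rate <- sum(w) / scale[j]
        if (rate <= 0) break
        wait <- stats::rexp(1, rate)
        if (wait > t_rem) break
        t_rem <- t_rem - wait
        s[j] <- nbm[sample.int(nrow(nbm), 1L, prob = w), "to"]
      }
    }
    seqs[[child]] <- s
  }
  to_str <- function(v) paste(tab$sense[v], collapse = "")
  leaf <- stats::setNames(vapply(seqs[seq_len(ntip)], to_str,
                                 character(1)), tree$tip.label)
  node <- stats::setNames(
    vapply(seqs[(ntip + 1L):(ntip + tree$Nnode)], to_str, character(1)),
    as.character((ntip + 1L):(ntip + tree$Nnode)))
  list(leaf = leaf, node = node, omega = omega)
}

# codon columns whose residue must stay fixed (omega 0): conserved sites
conserved_codon_columns <- function(exon_target, n_codons) {
  spec <- conserved_site_spec(exon_target)
  cols <- c(spec$cys_pair, as.integer(names(spec$termini_sites)))
  cols[cols >= 1 & cols <= n_codons]
}

# force required residues at conserved columns of a codon-index root
forced_root_codons <- function(exon_target, n_codons) {
  tab <- codon_model_tables()
  spec <- conserved_site_spec(exon_target)
  forced <- list()
  aa_codon <- function(aa) {
    # deterministic codon per amino acid
    cands <- tab$sense[tab$aa == aa]
    sort(cands)[1]
  }
  for (pos in spec$cys_pair) forced[[as.character(pos)]] <- aa_codon("C")
  ts <- spec$termini_sites
  for (k in seq_along(ts))
    forced[[names(ts)[k]]] <- aa_codon(ts[[k]])
  forced
}

mutate_to_neighbor <- function(codon_ids, columns_allowed, n_changes) {
  tab <- codon_model_tables()
  cols <- sample(columns_allowed, min(n_changes, length(columns_allowed)))
  for (j in cols) {
    nbm <- tab$neighbors[[codon_ids[j]]]
    codon_ids[j] <- nbm[sample.int(nrow(nbm), 1L), "to"]
  }
  codon_ids
}

#' Simulate a clone-amplicon dataset with ground truth
#'
#' Runs the full generative model (see the package vignette) and returns
#' paired-strand clone reads with metadata plus truth tables: true
#' variants per individual, planted chimeras (parents and breakpoints),
#' planted pseudogenes, trans-species clusters of the true variant set,
#' per-clone provenance and the per-site omega profiles.
#'
#' @param config [sim_config()].
#' @param seed integer master seed; all stage seeds derive from it.
#' @param out_dir optional directory; when given, \code{reads.fasta},
#'   \code{meta.tsv} and truth TSVs are written there.
#' @return list of class \code{sim_dataset}: \code{reads}, \code{truth}.
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1L,
                             out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  tax <- config$taxonomy
  tree <- config$species_tree
  tab <- codon_model_tables()
  reads_rows <- list()
  truth_variants <- list(); truth_chim <- list(); truth_pseudo <- list()
  truth_clones <- list(); omega_profiles <- list()
  ind_ids <- function(sp) sprintf("%s_i%d", sp,
                                  seq_len(config$individuals_per_species))

  for (target in names(config$targets)) {
    tg <- config$targets[[target]]
    n_codons <- (tg$length - tg$phase) %/% 3L
    phase_pad <- strrep("G", tg$phase)
    tail_pad <- strrep("A", (tg$length - tg$phase) %% 3L)
    # omega profile: background, elevated at PBR columns (exon 2),
    # zero at conserved columns
    omega <- rep(config$omega_background, n_codons)
    pbr <- pbr_sites(target)
    pbr <- pbr[pbr <= n_codons]
    omega[pbr] <- config$omega_pbr
    cons_cols <- conserved_codon_columns(target, n_codons)
    omega[cons_cols] <- 0
    omega_profiles[[target]] <- omega
    forced <- forced_root_codons(target, n_codons)

    # species allele pools per locus
    pools <- stats::setNames(
      replicate(nrow(tax), list(), simplify = FALSE), tax$gene_prefix)
    allele_seqs <- list()  # allele_id -> nt string
    add_allele <- function(sp, id, codon_str) {
      nt <- paste0(phase_pad, codon_str, tail_pad)
      allele_seqs[[id]] <<- nt
      pools[[sp]] <<- c(pools[[sp]], id)
    }
    for (locus in seq_len(tg$loci)) {
      sim_seed <- derive_seed(seed, paste0(target, "_locus", locus))
      set.seed(sim_seed)
      root <- sample.int(61L, n_codons, replace = TRUE)
      for (col in names(forced)) root[as.integer(col)] <-
          tab$idx[[forced[[col]]]]
      ev <- evolve_codon_sequences(tree, n_codons, omega = omega,
                                   kappa = config$kappa,
                                   seed = derive_seed(sim_seed, "evolve"),
                                   root_seq = paste(tab$sense[root],
                                                    collapse = ""))
      set.seed(derive_seed(sim_seed, "pools"))
      for (sp in tax$gene_prefix) {
        base_id <- sprintf("%s_%s_L%d_a1", sp, target, locus)
        add_allele(sp, base_id, ev$leaf[[sp]])
        if (config$within_species_alleles > 1L) {
          base_cd <- unname(tab$idx[codon_split(ev$leaf[[sp]])])
          allowed <- setdiff(seq_len(n_codons), cons_cols)
          for (a in 2:config$within_species_alleles) {
            der <- mutate_to_neighbor(base_cd, allowed, 2L)
            add_allele(sp, sprintf("%s_%s_L%d_a%d", sp, target, locus, a),
                       paste(tab$sense[der], collapse = ""))
          }
        }
      }
      # trans-species retention: copy ancestral alleles into descendants
      set.seed(derive_seed(sim_seed, "tsp"))
      ntip <- length(tree$tip.label)
      for (nd in (ntip + 2L):(ntip + tree$Nnode)) {
        if (stats::runif(1) > config$retention_rate) next
        desc <- ape::extract.clade(tree, nd)$tip.label
        if (length(desc) < 2L) next
        k <- sample(2:min(4L, length(desc)), 1L)
        chosen <- sample(desc, k)
        anc <- ev$node[[as.character(nd)]]
        for (m in seq_along(chosen))
          add_allele(chosen[m],
                     sprintf("%s_%s_L%d_tsp%d", chosen[m], target, locus,
                             nd), anc)
      }
      # pseudogenization
      set.seed(derive_seed(sim_seed, "pseudo"))
      for (sp in tax$gene_prefix) {
        if (stats::runif(1) > config$pseudogene_rate) next
        locus_ids <- grep(sprintf("_L%d_", locus), pools[[sp]],
                          value = TRUE)
        if (!length(locus_ids)) next
        vid <- sample(locus_ids, 1L)
        nt <- allele_seqs[[vid]]
        lesion <- sample(c("stop", "deletion"), 1L)
        site <- sample(5:(n_codons - 5L), 1L)
        if (lesion == "stop") {
          ntpos <- tg$phase + 3L * (site - 1L) + 1L
          substr(nt, ntpos, ntpos + 2L) <- "TAA"
        } else {
          ntpos <- tg$phase + 3L * (site - 1L) + 1L
          nt <- paste0(substr(nt, 1, ntpos - 1L),
                       substr(nt, ntpos + 1L, nchar(nt)))
        }
        allele_seqs[[vid]] <- nt
        truth_pseudo[[length(truth_pseudo) + 1L]] <- data.frame(
          species = sp, exon_target = target, allele_id = vid,
          lesion = lesion, aa_site = site, stringsAsFactors = FALSE)
      }
    }

    # diploid individuals, PCR, clones
    set.seed(derive_seed(seed, paste0(target, "_sampling")))
    for (sp in tax$gene_prefix) {
      pool <- pools[[sp]]
      for (ind in ind_ids(sp)) {
        # genotype: 2 haplotypes per locus, drawn from the locus pool
        geno <- character(0)
        for (locus in seq_len(tg$loci)) {
          lp <- grep(sprintf("_L%d_", locus), pool, value = TRUE)
          geno <- c(geno, sample(lp, 2L, replace = TRUE))
        }
        templates <- unique(geno)
        for (v in templates)
          truth_variants[[length(truth_variants) + 1L]] <- data.frame(
            species = sp, individual_id = ind, exon_target = target,
            allele_id = v, seq = allele_seqs[[v]],
            stringsAsFactors = FALSE)
        pcr <- sprintf("%s_%s", ind, target)
        rng <- seq(config$clones_per_individual[1],
                   config$clones_per_individual[length(
                     config$clones_per_individual)])
        n_clones <- if (length(rng) == 1L) rng else sample(rng, 1L)
        for (cl in seq_len(n_clones)) {
          clone_id <- sprintf("%s_c%d", pcr, cl)
          src <- sample(templates, 1L)
          cseq <- allele_seqs[[src]]
          is_chim <- FALSE; parents <- c(NA, NA); bp <- NA_integer_
          eq_len <- templates[nchar(unlist(allele_seqs[templates])) ==
                                nchar(cseq)]
          if (stats::runif(1) < config$chimera_rate &&
              length(eq_len) >= 2L) {
            pr <- sample(eq_len, 2L)
            L <- nchar(allele_seqs[[pr[1]]])
            bp <- sample(11:(L - 10L), 1L)
            cseq <- paste0(substr(allele_seqs[[pr[1]]], 1, bp),
                           substr(allele_seqs[[pr[2]]], bp + 1L, L))
            is_chim <- TRUE; parents <- pr; src <- NA_character_
            truth_chim[[length(truth_chim) + 1L]] <- data.frame(
              clone_id = clone_id, species = sp, individual_id = ind,
              exon_target = target, parent1 = pr[1], parent2 = pr[2],
              breakpoint = bp, stringsAsFactors = FALSE)
          }
          n_err <- stats::rbinom(1L, nchar(cseq), config$pcr_error_rate)
          if (n_err > 0L) {
            pos <- sample.int(nchar(cseq), n_err)
            cv <- strsplit(cseq, "")[[1]]
            for (p in pos)
              cv[p] <- sample(setdiff(c("A", "C", "G", "T"), cv[p]), 1L)
            cseq <- paste(cv, collapse = "")
          }
          truth_clones[[length(truth_clones) + 1L]] <- data.frame(
            clone_id = clone_id, species = sp, individual_id = ind,
            exon_target = target, source_allele = src,
            is_chimera = is_chim, n_errors = n_err, seq = cseq,
            stringsAsFactors = FALSE)
          for (dir in c("forward", "reverse")) {
            reads_rows[[length(reads_rows) + 1L]] <- data.frame(
              id = sprintf("%s_%s", clone_id,
                           if (dir == "forward") "F" else "R"),
              species = sp, individual_id = ind, pcr_id = pcr,
              direction = dir, exon_target = target,
              seq = if (dir == "forward") cseq else revcomp(cseq),
              clone_id = clone_id, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  reads <- do.call(rbind, reads_rows)
  class(reads) <- c("croc_reads", "data.frame")
  variants <- unique(do.call(rbind, truth_variants))
  truth <- list(
    variants = variants,
    chimeras = if (length(truth_chim)) do.call(rbind, truth_chim) else
      data.frame(clone_id = character(0), parent1 = character(0),
                 parent2 = character(0), breakpoint = integer(0)),
    pseudogenes = if (length(truth_pseudo)) do.call(rbind, truth_pseudo)
      else data.frame(species = character(0), allele_id = character(0),
                      lesion = character(0), aa_site = integer(0)),
    clones = do.call(rbind, truth_clones),
    tsp_clusters = true_tsp_clusters(variants, config),
    omega = omega_profiles
  )
  out <- structure(list(reads = reads, truth = truth, config = config,
                        seed = seed), class = "sim_dataset")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_reads(reads, file.path(out_dir, "reads.fasta"),
                file.path(out_dir, "meta.tsv"))
    utils::write.table(truth$variants, file.path(out_dir,
                                                 "truth_variants.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truth$clones, file.path(out_dir,
                                               "truth_clones.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

# trans-species clusters present in the true variant set: identical
# translated amplicons in >= 2 species, per target
true_tsp_clusters <- function(variants, config) {
  rows <- list()
  for (target in unique(variants$exon_target)) {
    phase <- config$targets[[target]]$phase
    grp <- variants[variants$exon_target == target, , drop = FALSE]
    aa <- vapply(grp$seq, translate_exon, character(1), phase = phase)
    by_aa <- split(grp$species, aa)
    for (s in names(by_aa)) {
      sps <- sort(unique(by_aa[[s]]))
      if (length(sps) >= 2L)
        rows[[length(rows) + 1L]] <- data.frame(
          exon_target = target, aa_seq = s, n_species = length(sps),
          species = paste(sps, collapse = ","), stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(exon_target = character(0), aa_seq = character(0),
               n_species = integer(0), species = character(0))
}
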