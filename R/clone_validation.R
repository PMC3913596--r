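# Clone-read validation: strand-consistency consensus, support screening,
# near-redundant singleton removal, within-individual PCR-chimera detection
# and Klein-style variant naming.
#
# Acceptance rule for a candidate sequence: present in >= min_support clones
# of one individual, and/or observed in more than one individual (within or
# across species). Artifact filters then discard unique sequences < 3 bp
# from a redundant sequence of the same PCR, and sequences explainable as a
# single-crossover combination of two other sequences of the same individual.

#' Build a consensus from a forward/reverse read pair
#'
#' The reverse read is reverse-complemented and compared position by
#' position with the forward read. IUPAC-compatible positions (non-empty
#' base-set intersection) count as agreement and resolve to the
#' intersection code; any incompatible position rejects the clone with rule
#' \code{strand_mismatch}.
#'
#' @param forward,reverse nucleotide strings (IUPAC); the reverse read as
#'   sequenced (it is reverse-complemented internally).
#' @return list with \code{seq} (consensus or \code{NULL}) and
#'   \code{rejection} (\code{NULL} or a one-row data.frame).
#' @export
build_consensus <- function(forward, reverse) {
  forward <- toupper(forward)
  rev_rc <- revcomp(toupper(reverse))
  if (nchar(forward) != nchar(rev_rc))
    stop2("reads do not overlap: lengths differ (",
          nchar(forward), " vs ", nchar(rev_rc), ")")
  fa <- strsplit(forward, "")[[1]]
  ra <- strsplit(rev_rc, "")[[1]]
  same <- fa == ra
  cons <- fa
  for (i in which(!same)) {
    code <- iupac_intersect(fa[i], ra[i])
    if (is.na(code)) {
      return(list(seq = NULL, rejection = data.frame(
        seq = forward, rule = "strand_mismatch",
        evidence = sprintf("position %d: %s vs %s", i, fa[i], ra[i]),
        stringsAsFactors = FALSE)))
    }
    cons[i] <- code
  }
  list(seq = paste(cons, collapse = ""), rejection = NULL)
}

# Pair forward/reverse reads per clone and build consensi.
# clone_id taken from reads$clone_id if present, else id minus _F/_R suffix.
consensus_from_reads <- function(reads) {
  clone <- if ("clone_id" %in% names(reads)) reads$clone_id
           else sub("_[FR]$", "", reads$id)
  rejections <- list()
  rows <- list()
  for (cl in unique(clone)) {
    grp <- reads[clone == cl, , drop = FALSE]
    fwd <- grp[grp$direction == "forward", , drop = FALSE]
    rev <- grp[grp$direction == "reverse", , drop = FALSE]
    if (nrow(fwd) == 0L || nrow(rev) == 0L)
      stop2("clone ", cl, " lacks a forward/reverse pair")
    res <- build_consensus(fwd$seq[1], rev$seq[1])
    if (is.null(res$seq)) {
      rej <- res$rejection
      rej$clone_id <- cl
      rejections[[length(rejections) + 1L]] <- rej
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        clone_id = cl, species = fwd$species[1],
        individual_id = fwd$individual_id[1], pcr_id = fwd$pcr_id[1],
        exon_target = fwd$exon_target[1], seq = res$seq, n_reads = 2L,
        stringsAsFactors = FALSE)
    }
  }
  list(consensus = if (length(rows)) do.call(rbind, rows) else NULL,
       rejections = if (length(rejections)) do.call(rbind, rejections)
                    else NULL)
}

#' Collapse identical consensus sequences and apply the support rule
#'
#' A sequence is a candidate variant of a species when it occurs in
#' \code{min_support} or more clones of one individual, and/or when it is
#' observed in more than one individual (within or across species). All
#' other sequences are flagged \code{singleton_unsupported}.
#'
#' @param consensus data.frame from [consensus_from_reads()] (columns
#'   \code{clone_id}, \code{species}, \code{individual_id}, \code{pcr_id},
#'   \code{exon_target}, \code{seq}).
#' @param min_support minimum within-individual clone count (default 2).
#' @return list with \code{candidates} (one row per species x sequence,
#'   support columns) and \code{rejections}.
#' @export
collapse_and_screen <- function(consensus, min_support = 2L) {
  stopifnot(nrow(consensus) >= 1L)
  key_ind <- paste(consensus$species, consensus$individual_id, sep = "\r")
  by_seq <- split(seq_len(nrow(consensus)), consensus$seq)
  cand <- list(); rej <- list()
  for (sq in names(by_seq)) {
    idx <- by_seq[[sq]]
    inds <- unique(key_ind[idx])
    per_ind <- table(key_ind[idx])
    accepted <- max(per_ind) >= min_support || length(inds) >= 2L
    for (sp in unique(consensus$species[idx])) {
      sp_idx <- idx[consensus$species[idx] == sp]
      if (accepted) {
        cand[[length(cand) + 1L]] <- data.frame(
          species = sp, seq = sq,
          n_clones = length(sp_idx),
          max_clones_one_individual = max(table(key_ind[sp_idx])),
          n_individuals = length(inds),
          individuals = paste(unique(consensus$individual_id[sp_idx]),
                              collapse = ","),
          pcr_ids = paste(unique(consensus$pcr_id[sp_idx]), collapse = ","),
          exon_target = consensus$exon_target[sp_idx[1]],
          clone_ids = paste(consensus$clone_id[sp_idx], collapse = ","),
          stringsAsFactors = FALSE)
      } else {
        rej[[length(rej) + 1L]] <- data.frame(
          seq = sq, rule = "singleton_unsupported",
          evidence = sprintf("species %s: 1 clone (%s), 1 individual", sp,
                             consensus$clone_id[sp_idx[1]]),
          species = sp, clone_id = consensus$clone_id[sp_idx[1]],
          pcr_id = consensus$pcr_id[sp_idx[1]],
          individual_id = consensus$individual_id[sp_idx[1]],
          stringsAsFactors = FALSE)
      }
    }
  }
  list(candidates = if (length(cand)) do.call(rbind, cand) else NULL,
       rejections = if (length(rej)) do.call(rbind, rej) else NULL)
}

# pairwise distance used by the <3 bp redundancy rule: Hamming for
# equal-length sequences, generalized edit distance (gaps count as
# differences) otherwise
seq_distance_bp <- function(a, b) {
  if (nchar(a) == nchar(b)) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  } else {
    as.integer(utils::adist(a, b))
  }
}

#' Discard near-redundant singletons (< 3 bp rule)
#'
#' Within each PCR product, a unique (single-clone) sequence lying less
#' than \code{threshold_bp} nucleotide differences from a redundant
#' (multi-clone) sequence of the same PCR is discarded as a likely PCR
#' point-error derivative.
#'
#' @param consensus consensus data.frame (see [collapse_and_screen()]).
#' @param accepted_seqs character vector of sequences already accepted by
#'   the support rule; when \code{exempt_rescued} is TRUE these are immune.
#' @param threshold_bp integer, default 3 ("less than 3 bp").
#' @param exempt_rescued apply the rule only to still-unsupported
#'   sequences (default TRUE; the filter runs after cross-individual
#'   rescue).
#' @return data.frame of rejection records (possibly 0 rows).
#' @export
filter_near_redundant <- function(consensus, accepted_seqs = character(0),
                                  threshold_bp = 3L,
                                  exempt_rescued = TRUE) {
  rej <- list()
  for (pcr in unique(consensus$pcr_id)) {
    grp <- consensus[consensus$pcr_id == pcr, , drop = FALSE]
    tab <- table(grp$seq)
    redundant <- names(tab)[tab >= 2L]
    unique_seqs <- names(tab)[tab == 1L]
    if (exempt_rescued)
      unique_seqs <- setdiff(unique_seqs, accepted_seqs)
    for (u in unique_seqs) {
      if (length(redundant) == 0L) next
      d <- vapply(redundant, seq_distance_bp, integer(1), a = u)
      hit <- which(d < threshold_bp & d > 0L)
      if (length(hit)) {
        rej[[length(rej) + 1L]] <- data.frame(
          seq = u, rule = "near_redundant_lt3bp",
          evidence = sprintf("pcr %s: %d bp from redundant sequence (%d clones)",
                             pcr, d[hit[1]], tab[redundant[hit[1]]]),
          pcr_id = pcr, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rej)) do.call(rbind, rej) else
    data.frame(seq = character(0), rule = character(0),
               evidence = character(0), pcr_id = character(0))
}

#' Flag within-individual PCR chimeras
#'
#' A sequence is flagged when it can be written exactly as
#' \code{P1[1..k] + P2[k+1..L]} for a single crossover point \code{k}
#' (1 <= k < L) and two other sequences P1 != P2 of the same individual.
#' PCR chimeras arise predominantly from a single template switch, hence
#' the one-crossover model.
#'
#' @param seqs named character vector: the candidate sequences of one
#'   individual (equal lengths assumed for the composition test).
#' @return data.frame with columns \code{name}, \code{parent1},
#'   \code{parent2}, \code{k_min}, \code{k_max} (the breakpoint interval
#'   over which the composition holds); 0 rows when nothing is flagged.
#' @export
detect_within_individual_chimeras <- function(seqs) {
  out <- data.frame(name = character(0), parent1 = character(0),
                    parent2 = character(0), k_min = integer(0),
                    k_max = integer(0), stringsAsFactors = FALSE)
  m <- length(seqs)
  if (m < 3L) return(out)
  chars <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  L <- unique(lengths(chars))
  if (length(L) != 1L) {
    # composition is only defined on equal lengths; compare within groups
    res <- lapply(split(seq_along(seqs), lengths(chars)), function(idx)
      detect_within_individual_chimeras(seqs[idx]))
    return(do.call(rbind, res))
  }
  nm <- names(seqs)
  for (v in seq_len(m)) {
    found <- FALSE
    for (p1 in seq_len(m)) {
      if (found) break
      if (p1 == v) next
      for (p2 in seq_len(m)) {
        if (p2 == v || p2 == p1) next
        if (identical(seqs[[p1]], seqs[[p2]])) next
        # k valid iff prefix of p1 matches v up to k and suffix of p2 after k
        pref <- chars[[v]] == chars[[p1]]
        suff <- chars[[v]] == chars[[p2]]
        pmax_ <- if (all(pref)) L else which(!pref)[1] - 1L
        smin_ <- if (all(suff)) 1L else max(which(!suff)) + 1L
        k_lo <- max(1L, smin_ - 1L)
        k_hi <- min(L - 1L, pmax_)
        if (k_lo <= k_hi &&
            !identical(seqs[[v]], seqs[[p1]]) &&
            !identical(seqs[[v]], seqs[[p2]])) {
          out <- rbind(out, data.frame(
            name = nm[v], parent1 = nm[p1], parent2 = nm[p2],
            k_min = k_lo, k_max = k_hi, stringsAsFactors = FALSE))
          found <- TRUE
          break
        }
      }
    }
  }
  out
}

#' Assign Klein-style variant names
#'
#' Accepted variants are named \code{<prefix>-<chain><nn>} (e.g.
#' \code{Crpo-DB01}): the four-letter gene prefix of the species, then
#' \code{DA} (class II alpha) or \code{DB} (class II beta), then a
#' zero-padded sequential id. Ordering is canonical - descending clone
#' support, then lexicographic sequence - so naming is independent of
#' input order.
#'
#' @param candidates data.frame with \code{species} (gene prefix),
#'   \code{seq} and \code{n_clones} columns.
#' @param taxonomy \code{croc_taxonomy} table.
#' @param chain \code{"DA"} or \code{"DB"}.
#' @return the data.frame with a \code{name} column added, reordered
#'   canonically.
#' @export
assign_names <- function(candidates, taxonomy, chain = c("DB", "DA")) {
  chain <- match.arg(chain)
  if (is.null(candidates) || nrow(candidates) == 0L)
    return(data.frame(name = character(0), species = character(0),
                      seq = character(0)))
  out <- list()
  for (sp in sort(unique(candidates$species))) {
    if (!sp %in% taxonomy$gene_prefix)
      stop2("species prefix not in taxonomy: ", sp)
    grp <- candidates[candidates$species == sp, , drop = FALSE]
    if (anyDuplicated(grp$seq))
      stop2("duplicate sequence within species ", sp, "/", chain)
    ord <- order(-grp$n_clones, grp$seq)
    grp <- grp[ord, , drop = FALSE]
    grp$name <- sprintf("%s-%s%02d", sp, chain, seq_len(nrow(grp)))
    out[[sp]] <- grp
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("name", setdiff(names(res), "name"))]
}

#' Full clone-validation pipeline
#'
#' Runs consensus building, support screening, the near-redundant
#' singleton filter, within-individual chimera removal and variant naming,
#' and partitions every input clone into either a validated variant's
#' support or exactly one rejection record.
#'
#' @param reads \code{croc_reads} data.frame (see
#'   [read_fasta_with_metadata()]).
#' @param taxonomy \code{croc_taxonomy}.
#' @param min_support within-individual clone support threshold (default 2).
#' @param redundancy_bp threshold of the near-redundancy rule (default 3).
#' @param exempt_rescued see [filter_near_redundant()].
#' @return list with \code{variants} (named, with support and chain),
#'   \code{rejections} and \code{consensus}.
#' @export
validate_clones <- function(reads, taxonomy, min_support = 2L,
                            redundancy_bp = 3L, exempt_rescued = TRUE) {
  step1 <- consensus_from_reads(reads)
  rejections <- list(step1$rejections)
  if (is.null(step1$consensus)) stop2("no strand-consistent clones")
  variants_all <- list()
  cons_all <- step1$consensus
  for (exon in unique(cons_all$exon_target)) {
    cons <- cons_all[cons_all$exon_target == exon, , drop = FALSE]
    step2 <- collapse_and_screen(cons, min_support = min_support)
    accepted_seqs <- if (!is.null(step2$candidates)) step2$candidates$seq
                     else character(0)
    rr <- filter_near_redundant(cons, accepted_seqs = accepted_seqs,
                                threshold_bp = redundancy_bp,
                                exempt_rescued = exempt_rescued)
    # drop candidates killed by the redundancy rule (when not exempted)
    cand <- step2$candidates
    if (!is.null(cand) && nrow(rr))
      cand <- cand[!cand$seq %in% rr$seq, , drop = FALSE]
    singles <- step2$rejections
    if (!is.null(singles) && nrow(rr))
      singles <- singles[!singles$seq %in% rr$seq, , drop = FALSE]
    if (nrow(rr)) rejections[[length(rejections) + 1L]] <-
      rr[, c("seq", "rule", "evidence")]

    # chimera screen per individual: a sequence is removed when it is an
    # exact single-crossover composition of two support-accepted
    # sequences of the same individual. Unsupported sequences (e.g.
    # singleton chimeric clones) are not eligible parents - otherwise a
    # pair of artefacts could "explain" a true variant.
    chim_rej <- list()
    if (!is.null(cand) && nrow(cand) >= 1L) {
      accepted_set <- unique(cand$seq)
      for (ind in unique(cons$individual_id)) {
        sub <- cons[cons$individual_id == ind, , drop = FALSE]
        seqs <- unique(sub$seq)
        if (length(seqs) < 3L) next
        # accepted sequences first so compositions via accepted parents
        # are found preferentially
        seqs <- c(intersect(seqs, accepted_set),
                  setdiff(seqs, accepted_set))
        names(seqs) <- paste0("s", seq_along(seqs))
        flags <- detect_within_individual_chimeras(seqs)
        if (nrow(flags) == 0L) next
        for (j in seq_len(nrow(flags))) {
          p1 <- seqs[[flags$parent1[j]]]
          p2 <- seqs[[flags$parent2[j]]]
          if (!(p1 %in% accepted_set && p2 %in% accepted_set)) next
          sq <- seqs[[flags$name[j]]]
          chim_rej[[length(chim_rej) + 1L]] <- data.frame(
            seq = sq, rule = "within_individual_chimera",
            evidence = sprintf(
              "individual %s: composition of two supported sequences, breakpoint in [%d,%d]",
              ind, flags$k_min[j], flags$k_max[j]),
            stringsAsFactors = FALSE)
        }
      }
    }
    if (length(chim_rej)) {
      chim <- do.call(rbind, chim_rej)
      chim <- chim[!duplicated(chim$seq), , drop = FALSE]
      if (!is.null(cand))
        cand <- cand[!cand$seq %in% chim$seq, , drop = FALSE]
      if (!is.null(singles)) {
        relabel <- singles$seq %in% chim$seq
        singles <- singles[!relabel, , drop = FALSE]
      }
      rejections[[length(rejections) + 1L]] <- chim
    }
    if (!is.null(singles) && nrow(singles))
      rejections[[length(rejections) + 1L]] <-
        singles[, c("seq", "rule", "evidence")]
    if (!is.null(cand) && nrow(cand)) {
      chain <- if (grepl("^IIa", exon)) "DA" else "DB"
      named <- assign_names(cand, taxonomy, chain = chain)
      named$chain <- chain
      variants_all[[exon]] <- named
    }
  }
  rejections <- rejections[!vapply(rejections, is.null, logical(1))]
  rej <- if (length(rejections))
    do.call(rbind, lapply(rejections, function(d)
      d[, c("seq", "rule", "evidence"), drop = FALSE]))
  else data.frame(seq = character(0), rule = character(0),
                  evidence = character(0))
  rownames(rej) <- NULL
  variants <- if (length(variants_all)) do.call(rbind, variants_all) else
    data.frame(name = character(0), species = character(0),
               seq = character(0))
  rownames(variants) <- NULL
  list(variants = variants, rejections = rej, consensus = cons_all)
}
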