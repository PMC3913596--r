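# Trans-species polymorphism (TSP) detection: identical translated
# sequences shared by two or more species, labelled sequentially and
# tallied per genus. Identity is exact string equality over the full
# translated amplicon, including 'X' and '*' characters, so pseudogenes
# participate. Within-species repeats count once toward the species set.

#' Detect trans-species polymorphisms
#'
#' A TSP cluster is one distinct amino-acid string observed in two or more
#' species of one dataset. Labels \code{TSP1, TSP2, ...} are assigned
#' globally across datasets: dataset order (\code{IIa_ex2},
#' \code{IIa_ex3}, \code{IIb_ex3}), then descending species count, then
#' lexicographic amino-acid string, so labelling is invariant to input
#' order.
#'
#' @param variants data.frame with \code{name}, \code{species} and
#'   \code{aa_seq} columns, plus \code{exon_target} defining the dataset.
#' @param dataset_order order in which datasets are numbered.
#' @return data.frame of class \code{tsp_clusters}: \code{label},
#'   \code{dataset}, \code{n_species}, \code{aa_seq}, \code{species}
#'   (comma-joined), \code{members} (comma-joined variant names).
#' @export
detect_tsps <- function(variants,
                        dataset_order = c("IIa_ex2", "IIa_ex3",
                                          "IIb_ex3")) {
  empty <- data.frame(label = character(0), dataset = character(0),
                      n_species = integer(0), aa_seq = character(0),
                      species = character(0), members = character(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("tsp_clusters", "data.frame")
  if (nrow(variants) == 0L) return(empty)
  if (!"exon_target" %in% names(variants))
    variants$exon_target <- dataset_order[1]
  rows <- list()
  for (ds in intersect(dataset_order, unique(variants$exon_target))) {
    grp <- variants[variants$exon_target == ds, , drop = FALSE]
    by_aa <- split(seq_len(nrow(grp)), grp$aa_seq)
    clusters <- Filter(function(idx)
      length(unique(grp$species[idx])) >= 2L, by_aa)
    if (length(clusters) == 0L) next
    n_sp <- vapply(clusters, function(idx)
      length(unique(grp$species[idx])), integer(1))
    ord <- order(-n_sp, names(clusters))
    for (j in ord) {
      idx <- clusters[[j]]
      rows[[length(rows) + 1L]] <- data.frame(
        dataset = ds, n_species = n_sp[j],
        aa_seq = names(clusters)[j],
        species = paste(sort(unique(grp$species[idx])), collapse = ","),
        members = paste(sort(grp$name[idx]), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$label <- paste0("TSP", seq_len(nrow(out)))
  out <- out[, c("label", "dataset", "n_species", "aa_seq", "species",
                 "members")]
  class(out) <- c("tsp_clusters", "data.frame")
  out
}

#' Tally TSP clusters per genus
#'
#' Produces a matrix shaped like a TSP summary table: one row per
#' cluster, the total species count N and the number of member species in
#' each genus (abbreviated to its first three letters, e.g. \code{Cro}
#' for Crocodylus).
#'
#' @param clusters output of [detect_tsps()].
#' @param taxonomy \code{croc_taxonomy} table.
#' @return data.frame: \code{label}, \code{dataset}, \code{N}, one column
#'   per genus, \code{members}.
#' @export
tally_tsps <- function(clusters, taxonomy) {
  genera <- unique(taxonomy$genus)
  codes <- substr(genera, 1, 3)
  out <- clusters[, c("label", "dataset"), drop = FALSE]
  out$N <- clusters$n_species
  counts <- matrix(0L, nrow(clusters), length(genera),
                   dimnames = list(NULL, codes))
  for (i in seq_len(nrow(clusters))) {
    sps <- strsplit(clusters$species[i], ",")[[1]]
    gen <- taxonomy$genus[match(sps, taxonomy$gene_prefix)]
    if (anyNA(gen))
      stop2("species not in taxonomy: ",
            paste(sps[is.na(gen)], collapse = ", "))
    tab <- table(substr(gen, 1, 3))
    counts[i, names(tab)] <- as.integer(tab)
  }
  stopifnot(all(rowSums(counts) == out$N))
  out <- cbind(out, as.data.frame(counts))
  out$members <- clusters$members
  rownames(out) <- NULL
  out
}
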