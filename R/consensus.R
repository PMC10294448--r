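# Weighted-lineage consensus taxonomy ("WEVOTE-style"): each classification
# source deposits its weight along the lineage of its voted taxid; the
# consensus is the deepest node holding a strict majority of the weight of
# the sources that produced a classification.

#' Consensus source weights
#'
#' The gene-derived (reference lookup) vote is trusted most: 60%, with 20%
#' each for the two short-read classifiers.
#'
#' @param gene_lookup,kaiju,centrifuge Positive weights summing to 1.
#' @return Named numeric vector of weights.
#' @export
consensus_weights <- function(gene_lookup = 0.6, kaiju = 0.2,
                              centrifuge = 0.2) {
  w <- c(gene_lookup = gene_lookup, kaiju = kaiju, centrifuge = centrifuge)
  if (any(w <= 0) || abs(sum(w) - 1) > 1e-9)
    stop("consensus weights must be positive and sum to 1")
  w
}

#' Taxonomic vote from a gene assignment
#'
#' Looks up the taxid of the assigned gene/protein via its accession;
#' unmapped accessions yield the unclassified taxid 0.
#'
#' @param read_id Read id(s).
#' @param gene_id Assigned gene/protein id(s), recycled against `read_id`.
#' @param accession_map Named integer map from [load_accession_map()].
#' @return `data.table` (`read_id`, `source` = "gene_lookup", `taxid`).
#' @export
gene_vote <- function(read_id, gene_id, accession_map) {
  taxid <- unname(accession_taxid(rep_len(gene_id, length(read_id)),
                                  accession_map))
  data.table::data.table(read_id = read_id, source = "gene_lookup",
                         taxid = taxid)
}

#' Read a short-read classifier output
#'
#' Kaiju/Centrifuge-like TSV: classified flag (`C`/`U`), read id, taxid.
#' Unclassified rows get taxid 0.
#'
#' @param path TSV path.
#' @param source Source label for the votes.
#' @return `data.table` (`read_id`, `source`, `taxid`).
#' @export
read_classifier_votes <- function(path, source) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 3L) stop("classifier file needs 3 columns (flag, read, taxid)")
  data.table::setnames(dt, 1:3, c("flag", "read_id", "taxid"))
  dt[, taxid := ifelse(flag == "U", 0L, as.integer(taxid))]
  dt[, .(read_id = as.character(read_id), source = source, taxid = taxid)]
}

# consensus for one read's votes; sources/taxids aligned vectors
consensus_one <- function(taxids, weights_used, tree) {
  nz <- taxids != 0L
  if (!any(nz)) return(0L)
  taxids <- taxids[nz]
  w <- weights_used[nz]
  W <- sum(w)
  lins <- lapply(taxids, function(t) lineage(tree, t))
  node <- unlist(lins)
  wt <- rep(w, lengths(lins))
  acc <- rowsum(wt, node)
  nodes <- as.integer(rownames(acc))
  depths <- vapply(nodes, function(n) length(lineage(tree, n)), integer(1))
  maj <- acc[, 1] > W / 2
  if (!any(maj)) return(tree$root)
  cand <- nodes[maj]
  cd <- depths[maj]
  deepest <- cand[cd == max(cd)]
  if (length(deepest) == 1L) deepest else lca(tree, deepest)
}

#' Weighted lineage consensus over classifier votes
#'
#' For each read, every source with a nonzero (classified) vote deposits its
#' weight on all nodes of the voted taxid's lineage. With `W` the total
#' weight of classified sources, the consensus is the deepest node whose
#' accumulated weight strictly exceeds `W/2`; equal-depth ties resolve to
#' the lowest common ancestor of the tied nodes. Reads with no classified
#' vote get taxid 0. Unclassified sources are excluded from `W` so that
#' absent votes do not dilute present ones.
#'
#' @param votes `data.table` (`read_id`, `source`, `taxid`); at most one vote
#'   per (read, source); taxid 0 means unclassified.
#' @param tree A `taxonomy_tree`; all nonzero taxids must be members.
#' @param weights Named weights from [consensus_weights()].
#' @return `data.table` (`read_id`, `taxid`).
#' @export
weighted_consensus <- function(votes, tree, weights = consensus_weights()) {
  stopifnot(all(c("read_id", "source", "taxid") %in% names(votes)))
  unknown_src <- setdiff(unique(votes$source), names(weights))
  if (length(unknown_src))
    stop("vote source(s) without weight: ", paste(unknown_src, collapse = ", "))
  if (anyDuplicated(votes, by = c("read_id", "source")))
    stop("more than one vote per (read, source)")
  nz <- votes$taxid != 0L
  if (any(nz)) {
    bad <- !vapply(unique(votes$taxid[nz]), function(t) has_taxid(tree, t),
                   logical(1))
    if (any(bad))
      stop("vote taxid(s) absent from taxonomy: ",
           paste(utils::head(unique(votes$taxid[nz])[bad], 3), collapse = ", "))
  }
  w <- weights
  votes[, .(taxid = consensus_one(taxid, unname(w[source]), tree)),
        by = "read_id"]
}

#' Tabulate read-pair counts per consensus taxon
#'
#' A fwd+rev pair contributes one count; merged reads and true singletons
#' also contribute one. Taxid 0 is reported as `Unclassified`.
#'
#' @param assignments `data.table` (`read_id`, `taxid`), one row per read id
#'   (pair level).
#' @param tree A `taxonomy_tree` (for names); may be `NULL` to report taxids
#'   only.
#' @return `data.table` (`taxid`, `taxon`, `read_pairs`), sorted by
#'   descending count.
#' @export
taxa_table <- function(assignments, tree = NULL) {
  if (nrow(assignments) == 0L)
    return(data.table::data.table(taxid = integer(), taxon = character(),
                                  read_pairs = integer()))
  if (anyDuplicated(assignments$read_id))
    stop("assignments must have one row per read (pair) id")
  out <- assignments[, .(read_pairs = .N), by = "taxid"]
  out[, taxon := if (is.null(tree)) as.character(taxid)
      else taxon_name(tree, taxid)]
  out[taxid == 0L, taxon := "Unclassified"]
  data.table::setorderv(out, "read_pairs", order = -1L)
  out[, c("taxid", "taxon", "read_pairs")]
}

#' Fraction of reads assigned at each taxonomic depth
#'
#' Each read is counted once at the rank of its consensus node; nodes with
#' unnamed ranks roll up to the nearest named ancestor. Reported levels are
#' species, genus, family-or-higher, and unclassified; the fractions sum
#' to 1.
#'
#' @param taxids Integer vector of per-read consensus taxids (0 allowed).
#' @param tree A `taxonomy_tree`.
#' @return Named numeric vector
#'   `(species, genus, family_or_higher, unclassified)`.
#' @export
rank_breakdown <- function(taxids, tree) {
  n <- length(taxids)
  if (n == 0L)
    return(c(species = 0, genus = 0, family_or_higher = 0, unclassified = 0))
  level <- vapply(taxids, function(t) {
    if (t == 0L) return("unclassified")
    anc <- named_rank_ancestor(tree, t)
    if (is.na(anc)) return("family_or_higher")  # only root above
    r <- taxon_rank(tree, anc)
    if (r == "species") "species" else if (r == "genus") "genus"
    else "family_or_higher"
  }, "")
  tab <- table(factor(level, levels = c("species", "genus",
                                        "family_or_higher", "unclassified")))
  out <- as.numeric(tab) / n
  stats::setNames(out, names(tab))
}

#' Write the per-read consensus with lineage strings
#'
#' @param assignments `data.table` (`read_id`, `taxid`).
#' @param tree A `taxonomy_tree`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_consensus <- function(assignments, tree, path) {
  lin_str <- vapply(assignments$taxid, function(t) {
    if (t == 0L) return("Unclassified")
    paste(taxon_name(tree, lineage(tree, t)), collapse = ";")
  }, "")
  rk <- vapply(assignments$taxid, function(t) {
    if (t == 0L) "unclassified" else taxon_rank(tree, t)
  }, "")
  out <- data.table::data.table(read_id = assignments$read_id,
                                taxid = assignments$taxid,
                                rank = rk, lineage = lin_str)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
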