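# Fixtures built in code plus the independent brute-force oracles used by
# the oracle-equivalence tests. Oracles are written against the definitions,
# not against the package implementations.

# -- taxonomy fixtures -------------------------------------------------------

write_dmp <- function(nodes, names_txt, dir = tempfile("dmp")) {
  dir.create(dir, showWarnings = FALSE)
  nodes_path <- file.path(dir, "nodes.dmp")
  names_path <- file.path(dir, "names.dmp")
  writeLines(nodes, nodes_path)
  writeLines(names_txt, names_path)
  list(nodes = nodes_path, names = names_path)
}

dmp_node <- function(taxid, parent, rank) {
  paste0(taxid, "\t|\t", parent, "\t|\t", rank, "\t|")
}

dmp_name <- function(taxid, name) {
  paste0(taxid, "\t|\t", name, "\t|\t\t|\tscientific name\t|")
}

# 3-node minimal tree: root -> genus -> species
tiny_tree <- function() {
  f <- write_dmp(c(dmp_node(1, 1, "no rank"),
                   dmp_node(2, 1, "genus"),
                   dmp_node(3, 2, "species")),
                 c(dmp_name(1, "root"), dmp_name(2, "GenusA"),
                   dmp_name(3, "Species a")))
  load_taxonomy(f$nodes, f$names)
}

# 20-node fixture with mixed ranks and a no-rank internal node
fixture_tree <- function() {
  nodes <- c(dmp_node(1, 1, "no rank"),
             dmp_node(10, 1, "superkingdom"),
             dmp_node(20, 10, "phylum"),
             dmp_node(21, 10, "phylum"),
             dmp_node(30, 20, "class"),
             dmp_node(31, 21, "class"),
             dmp_node(40, 30, "order"),
             dmp_node(41, 31, "order"),
             dmp_node(50, 40, "family"),
             dmp_node(51, 41, "family"),
             dmp_node(55, 50, "subfamily"),   # unnamed rank -> no_rank
             dmp_node(60, 55, "genus"),
             dmp_node(61, 50, "genus"),
             dmp_node(62, 51, "genus"),
             dmp_node(70, 60, "species"),
             dmp_node(71, 60, "species"),
             dmp_node(72, 61, "species"),
             dmp_node(73, 62, "species"),
             dmp_node(74, 62, "species"),
             dmp_node(75, 62, "species"))
  ids <- c(1, 10, 20, 21, 30, 31, 40, 41, 50, 51, 55, 60, 61, 62,
           70, 71, 72, 73, 74, 75)
  f <- write_dmp(nodes, vapply(ids, function(i) dmp_name(i, paste0("n", i)), ""))
  load_taxonomy(f$nodes, f$names)
}

# oracle: chase parents iteratively, reverse
oracle_lineage <- function(tree, taxid) {
  out <- integer(0)
  cur <- taxid
  repeat {
    out <- c(out, cur)
    p <- unname(tree$parent[[as.character(cur)]])
    if (p == cur) break
    cur <- p
  }
  rev(out)
}

# oracle: deepest element of the intersection of lineage lists
oracle_lca <- function(tree, taxids) {
  lins <- lapply(taxids, function(t) oracle_lineage(tree, t))
  common <- Reduce(intersect, lins)
  depths <- vapply(common, function(n) length(oracle_lineage(tree, n)),
                   integer(1))
  common[which.max(depths)]
}

# -- readflow oracles --------------------------------------------------------

# oracle: classify each id by counting its memberships
oracle_disambiguate <- function(category_ids) {
  ids <- unique(unlist(category_ids))
  out <- lapply(category_ids, function(x) character(0))
  out$ambiguous <- character(0)
  for (id in ids) {
    in_cat <- names(category_ids)[vapply(category_ids, function(s) id %in% s,
                                         logical(1))]
    if (length(in_cat) >= 2) out$ambiguous <- c(out$ambiguous, id)
    else out[[in_cat]] <- c(out[[in_cat]], id)
  }
  out
}

# -- gene-annotation oracles -------------------------------------------------

# oracle: token-by-token CIGAR summation, independent tokenizer
oracle_cigar_coverage <- function(cigar, read_length) {
  total <- 0
  rest <- cigar
  while (nzchar(rest)) {
    m <- regexpr("^[0-9]+", rest)
    len <- as.numeric(substr(rest, 1, attr(m, "match.length")))
    op <- substr(rest, attr(m, "match.length") + 1, attr(m, "match.length") + 1)
    if (op %in% c("M", "=", "X")) total <- total + len
    rest <- substr(rest, attr(m, "match.length") + 2, nchar(rest))
  }
  min(total / read_length, 1)
}

random_cigar <- function() {
  n_ops <- sample(1:6, 1)
  ops <- sample(c("M", "I", "D", "S", "H", "=", "X"), n_ops, replace = TRUE)
  lens <- sample(1:80, n_ops, replace = TRUE)
  paste0(paste0(lens, ops, collapse = ""))
}

# oracle: three-clause boolean re-evaluation
oracle_accept_tabular <- function(identity, aln_len, bitscore, qlen,
                                  translated, thr) {
  eff <- if (translated) floor(qlen / 3) else qlen
  !(identity < thr$identity_min ||
      100 * aln_len / eff < thr$aln_len_fraction_min ||
      bitscore < thr$bitscore_min)
}

# oracle: linear scan, earliest strict improvement
oracle_best <- function(scores) {
  best <- 1
  for (i in seq_along(scores)) if (scores[i] > scores[best]) best <- i
  best
}

# -- consensus oracle --------------------------------------------------------

# brute-force accumulator: weight every node of every vote lineage, pick the
# deepest strict-majority node, ties -> lca
oracle_consensus <- function(taxids, weights, tree) {
  nz <- taxids != 0
  if (!any(nz)) return(0L)
  taxids <- taxids[nz]; weights <- weights[nz]
  W <- sum(weights)
  acc <- list()
  for (i in seq_along(taxids)) {
    for (n in oracle_lineage(tree, taxids[i])) {
      k <- as.character(n)
      acc[[k]] <- (if (is.null(acc[[k]])) 0 else acc[[k]]) + weights[i]
    }
  }
  nodes <- as.integer(names(acc))
  w <- unlist(acc)
  maj <- nodes[w > W / 2]
  if (length(maj) == 0) return(tree$root)
  d <- vapply(maj, function(n) length(oracle_lineage(tree, n)), integer(1))
  deepest <- maj[d == max(d)]
  if (length(deepest) == 1) deepest else oracle_lca(tree, deepest)
}

# -- rollup oracle -----------------------------------------------------------

# hand replay of the merge rule: above-cutoff taxa emitted at own rank;
# sub-cutoff taxa pooled with sub-cutoff relatives rank by rank; leftovers
# to Other. Returns total count per emitted label for comparison.
oracle_rollup <- function(taxids, counts, tree, cutoff) {
  total <- sum(counts)
  res <- list()
  pend_tax <- c(); pend_cnt <- c()
  for (i in seq_along(taxids)) {
    if (counts[i] / total >= cutoff) {
      lin <- oracle_lineage(tree, taxids[i])
      named <- lin[unname(tree$rank[as.character(lin)]) %in%
                     c("species", "genus", "family", "order", "class",
                       "phylum", "superkingdom")]
      node <- if (length(named)) named[length(named)] else taxids[i]
      k <- as.character(node)
      res[[k]] <- (if (is.null(res[[k]])) 0 else res[[k]]) + counts[i]
    } else {
      pend_tax <- c(pend_tax, taxids[i]); pend_cnt <- c(pend_cnt, counts[i])
    }
  }
  for (rk in c("genus", "family", "order", "class", "phylum")) {
    if (!length(pend_tax)) break
    anc <- vapply(pend_tax, function(t) {
      lin <- oracle_lineage(tree, t)
      hit <- lin[unname(tree$rank[as.character(lin)]) == rk]
      if (length(hit)) hit[length(hit)] else NA_integer_
    }, integer(1))
    keep_tax <- c(); keep_cnt <- c()
    for (a in unique(anc[!is.na(anc)])) {
      s <- sum(pend_cnt[!is.na(anc) & anc == a])
      if (s / total >= cutoff) {
        k <- as.character(a)
        res[[k]] <- (if (is.null(res[[k]])) 0 else res[[k]]) + s
      } else {
        keep_tax <- c(keep_tax, a); keep_cnt <- c(keep_cnt, s)
      }
    }
    keep_tax <- c(keep_tax, pend_tax[is.na(anc)])
    keep_cnt <- c(keep_cnt, pend_cnt[is.na(anc)])
    pend_tax <- keep_tax; pend_cnt <- keep_cnt
  }
  if (length(pend_tax)) res[["Other"]] <- sum(pend_cnt)
  res
}

# -- misc --------------------------------------------------------------------

make_read_set <- function(n, read_length = 20, paired = TRUE, seed = 1) {
  set.seed(seed)
  ids <- sprintf("r%04d", seq_len(n))
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), read_length, replace = TRUE),
          collapse = ""), "")
  qual <- strrep("I", read_length)
  if (paired) {
    data.table::rbindlist(list(
      read_table(ids, "fwd", seqs, qual),
      read_table(ids, "rev", rev(seqs), qual)))
  } else read_table(ids, "single", seqs, qual)
}
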