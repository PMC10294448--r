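# Report generation: read summary, RPKM expression tables, taxon rollup,
# Cytoscape EC table, superpathway matrix, assembly stats and quality
# histograms.

#' Reads per kilobase of transcript per million mapped reads
#'
#' `read_count * 1e9 / (gene_length_bp * total_mapped_reads)`.
#'
#' @param read_count Reads assigned to the gene (vector allowed).
#' @param gene_length_bp Gene length in nucleotides (>= 1). For protein
#'   (translated-tier) hits pass 3x the protein length.
#' @param total_mapped_reads Total annotated reads in the sample (>= 1).
#' @return Numeric RPKM value(s).
#' @export
rpkm <- function(read_count, gene_length_bp, total_mapped_reads) {
  if (any(gene_length_bp < 1)) stop("gene_length_bp must be >= 1")
  if (any(total_mapped_reads < 1)) stop("total_mapped_reads must be >= 1")
  read_count * 1e9 / (gene_length_bp * total_mapped_reads)
}

#' Gene expression table with RPKM, taxonomy and EC annotations
#'
#' @param gene_map Gene-to-read map (`gene_id`, `read_id`, `tier`, `n_mates`).
#' @param gene_lengths Named integer vector gene id -> length (bp; use 3x
#'   protein length for translated-tier subjects).
#' @param gene_taxids Named integer vector gene id -> taxid (optional).
#' @param ec_annotations EC table (`target_id`, `ec`) keyed by gene (optional).
#' @return `data.table` (`gene_id`, `length_bp`, `read_count`, `rpkm`,
#'   `taxid`, `ec_list`).
#' @export
expression_table <- function(gene_map, gene_lengths, gene_taxids = NULL,
                             ec_annotations = NULL) {
  if (nrow(gene_map) == 0L)
    return(data.table::data.table(gene_id = character(), length_bp = integer(),
                                  read_count = numeric(), rpkm = numeric(),
                                  taxid = integer(), ec_list = character()))
  tab <- gene_map[, .(read_count = sum(n_mates)), by = "gene_id"]
  tab[, length_bp := as.integer(gene_lengths[gene_id])]
  if (anyNA(tab$length_bp))
    stop("missing gene length for: ",
         paste(utils::head(tab$gene_id[is.na(tab$length_bp)], 3), collapse = ", "))
  total <- sum(tab$read_count)
  tab[, rpkm := rpkm(read_count, length_bp, total)]
  tab[, taxid := if (is.null(gene_taxids)) NA_integer_
      else as.integer(gene_taxids[gene_id])]
  if (!is.null(ec_annotations) && nrow(ec_annotations)) {
    ecs <- ec_annotations[, .(ec_list = paste(sort(unique(ec)), collapse = ",")),
                          by = "target_id"]
    tab[, ec_list := ecs$ec_list[match(gene_id, ecs$target_id)]]
  } else tab[, ec_list := NA_character_]
  tab[is.na(ec_list), ec_list := ""]
  tab[, c("gene_id", "length_bp", "read_count", "rpkm", "taxid", "ec_list")]
}

#' Merge low-abundance taxa into higher-rank groups
#'
#' Starting at species, a taxon meeting the cutoff fraction of total reads is
#' emitted as its own group at its (deepest named) rank. Sub-cutoff taxa are
#' merged with other sub-cutoff taxa sharing their genus; groups meeting the
#' cutoff are emitted there, and the merge repeats through family, order,
#' class and phylum. Whatever is still below the cutoff at phylum is pooled
#' into `Other`. Unclassified reads (taxid 0) form their own group.
#'
#' @param taxon_counts `data.table` (`taxid`, `read_pairs`) — e.g. a
#'   [taxa_table()].
#' @param tree A `taxonomy_tree`.
#' @param cutoff_fraction Minimum fraction of total reads for a group
#'   (default 0.01).
#' @return `data.table` (`label`, `taxid`, `rank`, `read_pairs`,
#'   `read_fraction`, `member_taxids` comma-joined).
#' @export
rollup_taxa <- function(taxon_counts, tree, cutoff_fraction = 0.01) {
  stopifnot(all(taxon_counts$read_pairs >= 0))
  empty <- data.table::data.table(label = character(), taxid = integer(),
                                  rank = character(), read_pairs = numeric(),
                                  read_fraction = numeric(),
                                  member_taxids = character())
  total <- sum(taxon_counts$read_pairs)
  if (total == 0) return(empty)
  groups <- list()
  emit <- function(label, taxid, rank, count, members) {
    groups[[length(groups) + 1L]] <<- data.table::data.table(
      label = label, taxid = taxid, rank = rank, read_pairs = count,
      read_fraction = count / total,
      member_taxids = paste(members, collapse = ","))
  }
  unc <- taxon_counts[taxon_counts$taxid == 0L]
  if (nrow(unc) && sum(unc$read_pairs) > 0)
    emit("Unclassified", 0L, "unclassified", sum(unc$read_pairs), 0L)
  work <- taxon_counts[taxon_counts$taxid != 0L & taxon_counts$read_pairs > 0]
  if (nrow(work) == 0L)
    return(data.table::rbindlist(groups))
  # pending: taxid of current group anchor, count, member leaves
  pending <- lapply(seq_len(nrow(work)), function(i)
    list(taxid = work$taxid[i], count = work$read_pairs[i],
         members = work$taxid[i]))
  # emit anything already at/above cutoff at its own named rank
  ranks_up <- c("genus", "family", "order", "class", "phylum")
  keep_pending <- list()
  for (p in pending) {
    anc <- named_rank_ancestor(tree, p$taxid)
    if (p$count / total >= cutoff_fraction) {
      node <- if (is.na(anc)) p$taxid else anc
      emit(taxon_name(tree, node), node, taxon_rank(tree, node), p$count,
           p$members)
    } else keep_pending[[length(keep_pending) + 1L]] <- p
  }
  pending <- keep_pending
  for (rk in ranks_up) {
    if (length(pending) == 0L) break
    anchor <- vapply(pending, function(p)
      ancestor_at_rank(tree, p$taxid, rk), integer(1))
    nxt <- list()
    for (a in unique(anchor[!is.na(anchor)])) {
      idx <- which(!is.na(anchor) & anchor == a)
      cnt <- sum(vapply(pending[idx], `[[`, numeric(1), "count"))
      members <- unlist(lapply(pending[idx], `[[`, "members"))
      if (cnt / total >= cutoff_fraction)
        emit(taxon_name(tree, a), a, rk, cnt, members)
      else
        nxt[[length(nxt) + 1L]] <- list(taxid = a, count = cnt,
                                        members = members)
    }
    # taxa with no ancestor at this rank stay pending unchanged
    for (i in which(is.na(anchor))) nxt[[length(nxt) + 1L]] <- pending[[i]]
    pending <- nxt
  }
  if (length(pending)) {
    cnt <- sum(vapply(pending, `[[`, numeric(1), "count"))
    members <- unlist(lapply(pending, `[[`, "members"))
    emit("Other", NA_integer_, "other", cnt, members)
  }
  out <- data.table::rbindlist(groups)
  data.table::setorderv(out, "read_pairs", order = -1L)
  out
}

#' Per-EC expression broken down by taxon group (Cytoscape import table)
#'
#' One row per expressed EC with its total RPKM and one column per taxon
#' group; group columns sum to the EC total. ECs with zero RPKM are omitted.
#'
#' @param expr Expression table from [expression_table()] (needs nonempty
#'   `ec_list` rows and `taxid`).
#' @param groups Rollup from [rollup_taxa()]; each gene's taxid is matched to
#'   the group containing it as a member (unmatched taxa fall into `Other`,
#'   or an `Other` column is added as needed).
#' @param path Optional output TSV path.
#' @return `data.table` with `ec`, `total_rpkm`, then one column per group
#'   label.
#' @export
cytoscape_table <- function(expr, groups, path = NULL) {
  long <- ec_rpkm_by_group(expr, groups)
  if (nrow(long) == 0L) {
    out <- data.table::data.table(ec = character(), total_rpkm = numeric())
    if (!is.null(path)) data.table::fwrite(out, path, sep = "\t")
    return(out)
  }
  wide <- data.table::dcast(long, ec ~ label, value.var = "rpkm",
                            fun.aggregate = sum, fill = 0)
  tot <- long[, .(total_rpkm = sum(rpkm)), by = "ec"]
  out <- merge(tot, wide, by = "ec")
  out <- out[out$total_rpkm > 0]
  data.table::setorderv(out, "total_rpkm", order = -1L)
  if (!is.null(path)) data.table::fwrite(out, path, sep = "\t")
  out
}

# long table (ec, label, rpkm): expression per EC per taxon group
ec_rpkm_by_group <- function(expr, groups) {
  rows <- expr[nzchar(expr$ec_list)]
  if (nrow(rows) == 0L)
    return(data.table::data.table(ec = character(), label = character(),
                                  rpkm = numeric()))
  member_of <- group_membership(groups)
  long <- rows[, .(ec = strsplit(ec_list, ",", fixed = TRUE)[[1]],
                   rpkm = rpkm, taxid = taxid), by = "gene_id"]
  long[, label := member_of(taxid)]
  long[, .(rpkm = sum(rpkm)), by = c("ec", "label")]
}

# closure mapping a taxid to its rollup group label ("Other" if unmatched)
group_membership <- function(groups) {
  if (nrow(groups) == 0L) return(function(taxid) rep("Other", length(taxid)))
  map <- list()
  for (i in seq_len(nrow(groups))) {
    for (m in strsplit(groups$member_taxids[i], ",", fixed = TRUE)[[1]])
      map[[m]] <- groups$label[i]
  }
  function(taxid) {
    out <- vapply(as.character(taxid), function(t) {
      v <- map[[t]]
      if (is.null(v)) "Other" else v
    }, "", USE.NAMES = FALSE)
    out[is.na(taxid)] <- "Other"
    out
  }
}

#' Superpathway-by-taxon expression matrix
#'
#' Cells hold the summed RPKM of each taxon group's ECs within each
#' superpathway; ECs mapping to several superpathways are counted in each.
#' ECs absent from the map contribute to an `Unmapped` row. Taxon groups are
#' ranked by their total read count; the `top_n` most prevalent are retained
#' and the remainder summed into an `Other` column.
#'
#' @param ec_rpkm_by_taxon `data.table` (`ec`, `label`, `rpkm`) — e.g. from
#'   the long form used by [cytoscape_table()].
#' @param ec_to_superpathway `data.table` (`ec`, `superpathway`), possibly
#'   many-to-many.
#' @param group_read_counts Named numeric vector: taxon-group label -> total
#'   read count (used for prevalence ranking).
#' @param top_n Number of taxon columns to keep (default 20).
#' @param path Optional output CSV path (`EC_coverage.csv`-style).
#' @return Matrix (superpathway x taxon group).
#' @export
superpathway_matrix <- function(ec_rpkm_by_taxon, ec_to_superpathway,
                                group_read_counts, top_n = 20L, path = NULL) {
  dt <- data.table::as.data.table(ec_rpkm_by_taxon)
  if (nrow(dt) == 0L) return(matrix(numeric(), 0, 0))
  spm <- data.table::as.data.table(ec_to_superpathway)
  long <- merge(dt, spm, by = "ec", all.x = TRUE, allow.cartesian = TRUE)
  long[is.na(superpathway), superpathway := "Unmapped"]
  ranked <- names(sort(group_read_counts, decreasing = TRUE))
  keep <- utils::head(ranked, top_n)
  long[, col := ifelse(label %in% keep, label, "Other")]
  cells <- long[, .(rpkm = sum(rpkm)), by = c("superpathway", "col")]
  wide <- data.table::dcast(cells, superpathway ~ col, value.var = "rpkm",
                            fill = 0)
  mat <- as.matrix(wide[, -1, with = FALSE])
  rownames(mat) <- wide$superpathway
  col_order <- c(intersect(keep, colnames(mat)),
                 intersect("Other", colnames(mat)))
  mat <- mat[, col_order, drop = FALSE]
  if (!is.null(path)) {
    out <- data.table::data.table(superpathway = rownames(mat))
    for (cn in colnames(mat)) out[[cn]] <- mat[, cn]
    data.table::fwrite(out, path)
  }
  mat
}

#' The 16-field read summary
#'
#' Counters and percentages describing the fate of every read: total, high
#' quality (+%), host (+%), vector (+%), rRNA/tRNA (+%), putative mRNA (+%),
#' annotated (+%, relative to putative mRNA), unique genes, unique ECs at
#' high and at low stringency. Percentages recompute exactly from their
#' numerators.
#'
#' @param ledger A complete read ledger (see [ledger_counts()]).
#' @param gene_map Gene-to-read map from [cascade_annotate()].
#' @param ec_counts Named vector `c(low = ..., high = ...)` of unique-EC
#'   counts (e.g. `n_unique_ec` from [ec_reports()]).
#' @param path Optional output TSV path.
#' @return Named list of the 16 fields.
#' @export
read_summary <- function(ledger, gene_map, ec_counts = c(low = 0, high = 0),
                         path = NULL) {
  total <- nrow(ledger)
  cnt <- if (total) ledger_counts(ledger) else
    stats::setNames(integer(length(TERMINAL_CATEGORIES)), TERMINAL_CATEGORIES)
  pct <- function(x) if (total == 0) 0 else 100 * x / total
  high_quality <- total - cnt[["low_quality"]]
  putative <- cnt[["annotated"]] + cnt[["unidentified"]]
  annotated <- cnt[["annotated"]]
  out <- list(
    total_reads = total,
    high_quality_reads = high_quality,
    high_quality_pct = pct(high_quality),
    host_reads = cnt[["host"]],
    host_pct = pct(cnt[["host"]]),
    vector_reads = cnt[["vector"]],
    vector_pct = pct(cnt[["vector"]]),
    rRNA_tRNA_reads = cnt[["rRNA_tRNA"]],
    rRNA_tRNA_pct = pct(cnt[["rRNA_tRNA"]]),
    putative_mRNA_reads = putative,
    putative_mRNA_pct = pct(putative),
    annotated_reads = annotated,
    annotated_pct = if (putative == 0) 0 else 100 * annotated / putative,
    unique_genes = length(unique(gene_map$gene_id)),
    unique_ec_high = unname(ec_counts[["high"]]),
    unique_ec_low = unname(ec_counts[["low"]]))
  if (putative > total) stop("invariant violated: putative mRNA > total reads")
  if (!is.null(path)) {
    dt <- data.table::data.table(field = names(out),
                                 value = unlist(out, use.names = FALSE))
    data.table::fwrite(dt, path, sep = "\t")
  }
  out
}

#' N50 and L50 of a set of contig lengths
#'
#' Lengths are sorted in decreasing order; N50 is the first length at which
#' the cumulative sum reaches half the total, L50 the number of contigs used
#' to get there.
#'
#' @param contig_lengths Nonempty vector of positive integers.
#' @return Named list `(N50, L50)`.
#' @export
n50_l50 <- function(contig_lengths) {
  if (length(contig_lengths) == 0L) stop("n50_l50: empty length list")
  stopifnot(all(contig_lengths > 0))
  s <- sort(contig_lengths, decreasing = TRUE)
  cum <- cumsum(s)
  i <- which(cum >= sum(s) / 2)[1]
  list(N50 = s[i], L50 = i)
}

#' Read-quality histogram before and after filtering
#'
#' Per-read mean phred scores binned into integer bins 0-41; bin counts sum
#' to the read counts of each file.
#'
#' @param fastq_before,fastq_after FASTQ paths.
#' @param path Optional output TSV path.
#' @return `data.table` (`bin`, `before`, `after`) over bins 0..41.
#' @export
quality_histogram <- function(fastq_before, fastq_after, path = NULL) {
  bins <- 0:41
  one <- function(p) {
    reads <- read_fastq(p)
    if (nrow(reads) == 0L) return(stats::setNames(integer(42), bins))
    b <- pmin(pmax(floor(mean_phred(reads$quality)), 0), 41)
    tab <- table(factor(b, levels = bins))
    stats::setNames(as.integer(tab), bins)
  }
  out <- data.table::data.table(bin = bins, before = one(fastq_before),
                                after = one(fastq_after))
  if (!is.null(path)) data.table::fwrite(out, path, sep = "\t")
  out
}
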