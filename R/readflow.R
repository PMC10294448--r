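# Read bookkeeping: every read travels through filter categories and must end
# in exactly one terminal category, so that terminal counts sum to the raw
# input count.

TERMINAL_CATEGORIES <- c("low_quality", "host", "vector", "rRNA_tRNA",
                         "annotated", "unidentified")
FILTER_CATEGORIES <- c("host", "vector", "rRNA_tRNA")

#' Construct a read table
#'
#' Reads are represented as a `data.table` with columns `read_id`, `mate`
#' (`fwd`, `rev`, `merged` or `single`), `sequence` and `quality`
#' (phred+33, same length as the sequence).
#'
#' @param read_id Character vector of read identifiers (pair mates share one id).
#' @param mate Character vector in `{fwd, rev, merged, single}`.
#' @param sequence Nucleotide strings.
#' @param quality Phred quality strings, same lengths as `sequence`.
#' @return A `data.table` of reads.
#' @export
read_table <- function(read_id, mate = "single", sequence, quality) {
  stopifnot(all(nzchar(read_id)))
  mate <- rep_len(mate, length(read_id))
  if (!all(mate %in% c("fwd", "rev", "merged", "single")))
    stop("mate must be one of fwd, rev, merged, single")
  if (!all(nchar(sequence) == nchar(quality)))
    stop("sequence and quality lengths differ")
  data.table::data.table(read_id = read_id, mate = mate,
                         sequence = sequence, quality = quality)
}

#' Read a FASTQ file into a read table
#'
#' Uses Biostrings for parsing. The mate label is taken from a trailing
#' `/1` / `/2` on the record id when present, otherwise from the `mate`
#' argument.
#'
#' @param path FASTQ file (phred+33).
#' @param mate Default mate label for records without `/1`/`/2` suffix.
#' @return A read `data.table` (see [read_table()]).
#' @export
read_fastq <- function(path, mate = "single") {
  # Biostrings warns about dropping its own mcols during construction here
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  ids <- names(x)
  ids <- sub("\\s.*$", "", ids)
  mates <- rep(mate, length(ids))
  suffixed <- grepl("/[12]$", ids)
  mates[suffixed] <- ifelse(grepl("/1$", ids[suffixed]), "fwd", "rev")
  ids <- sub("/[12]$", "", ids)
  read_table(read_id = ids, mate = mates,
             sequence = as.character(x),
             quality = as.character(Biostrings::quality(x)))
}

#' Write a read table to FASTQ
#'
#' `fwd`/`rev` mates get `/1`/`/2` id suffixes so pairing survives the
#' round-trip.
#'
#' @param reads A read `data.table`.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  ids <- reads$read_id
  ids[reads$mate == "fwd"] <- paste0(ids[reads$mate == "fwd"], "/1")
  ids[reads$mate == "rev"] <- paste0(ids[reads$mate == "rev"], "/2")
  dna <- Biostrings::DNAStringSet(stats::setNames(reads$sequence, ids))
  Biostrings::writeXStringSet(dna, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

#' Mean phred score per read
#' @param quality Phred+33 quality strings.
#' @return Numeric vector of mean phred scores (NaN for empty strings).
#' @export
mean_phred <- function(quality) {
  vapply(quality, function(q) mean(utf8ToInt(q)) - 33, numeric(1),
         USE.NAMES = FALSE)
}

# ---- ledger ----------------------------------------------------------------

#' Initialise a read ledger
#'
#' The ledger tracks the category trajectory of every read (per mate). All
#' reads start in category `raw`; filters append categories; exactly one
#' terminal category must be reached per read before the ledger is valid.
#'
#' @param reads A read `data.table`.
#' @return A `data.table` ledger keyed by (`read_id`, `mate`) with columns
#'   `trajectory` (">"-joined category path) and `terminal` (NA until final).
#' @export
ledger_init <- function(reads) {
  led <- data.table::data.table(read_id = reads$read_id, mate = reads$mate,
                                trajectory = "raw", terminal = NA_character_)
  data.table::setkeyv(led, c("read_id", "mate"))
  if (anyDuplicated(led, by = c("read_id", "mate")))
    stop("duplicate (read_id, mate) in input reads")
  led
}

#' Record a category step in the ledger
#'
#' @param ledger A ledger from [ledger_init()].
#' @param read_id,mate Identify the reads to advance (vectors, recycled
#'   against each other).
#' @param category Category to append; if terminal, the `terminal` column is
#'   set and further advances error out.
#' @return The ledger, modified by reference and returned invisibly.
#' @export
ledger_record <- function(ledger, read_id, mate, category) {
  stopifnot(length(category) == 1L)
  if (length(read_id) == 0L) return(invisible(ledger))
  lookup <- data.table::data.table(read_id = read_id, mate = mate)
  i <- ledger[lookup, on = c("read_id", "mate"), which = TRUE]
  if (anyNA(i))
    stop("ledger_record: unknown read(s): ",
         paste(utils::head(read_id[is.na(i)], 3), collapse = ", "))
  if (any(!is.na(ledger$terminal[i])))
    stop("ledger_record: read already in a terminal category")
  data.table::set(ledger, i, "trajectory",
                  paste0(ledger$trajectory[i], ">", category))
  if (category %in% TERMINAL_CATEGORIES)
    data.table::set(ledger, i, "terminal", category)
  invisible(ledger)
}

#' Terminal category counts of a complete ledger
#'
#' Errors if any read has not reached a terminal category; the returned counts
#' sum to the number of ledger rows (read conservation).
#'
#' @param ledger A ledger.
#' @return Named integer vector of counts over the terminal categories.
#' @export
ledger_counts <- function(ledger) {
  if (anyNA(ledger$terminal))
    stop("ledger incomplete: ", sum(is.na(ledger$terminal)),
         " read(s) without a terminal category")
  tab <- table(factor(ledger$terminal, levels = TERMINAL_CATEGORIES))
  stats::setNames(as.integer(tab), names(tab))
}

#' Export a ledger to TSV
#' @param ledger A ledger.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
ledger_write <- function(ledger, path) {
  out <- ledger[, c("read_id", "mate", "terminal", "trajectory")]
  data.table::setnames(out, "terminal", "terminal_category")
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

# ---- pairing rules ---------------------------------------------------------

#' Promote orphans after a per-mate filter
#'
#' For paired reads with per-mate pass/fail flags: pairs where both mates pass
#' stay paired; where exactly one passes, the survivor becomes a singleton
#' (an orphan); where neither passes, both are removed.
#'
#' @param reads A read `data.table` of `fwd`/`rev` mates.
#' @param pass Logical vector along `reads` rows: did that mate pass?
#' @return List with read tables `pairs`, `singletons` (mate relabelled
#'   `single`), and `removed`.
#' @export
promote_orphans <- function(reads, pass) {
  stopifnot(nrow(reads) == length(pass))
  if (!all(reads$mate %in% c("fwd", "rev")))
    stop("promote_orphans expects fwd/rev mates only")
  dt <- data.table::copy(reads)
  dt[, `.pass` := pass]
  n_pass <- dt[, .(k = sum(`.pass`)), by = "read_id"]
  both <- n_pass$read_id[n_pass$k == 2L]
  one  <- n_pass$read_id[n_pass$k == 1L]
  pairs <- dt[dt$read_id %in% both]
  singles <- dt[dt$read_id %in% one & dt$`.pass`]
  singles[, mate := "single"]
  removed <- dt[!dt$`.pass`]
  for (x in list(pairs, singles, removed)) x[, `.pass` := NULL]
  list(pairs = pairs, singletons = singles, removed = removed)
}

#' Apply a host/vector/rRNA filter to a read pair under a stringency mode
#'
#' In `high` stringency (the default behaviour), if either mate hits the
#' filter database both mates are assigned the filter category. In `low`
#' stringency only hitting mates are filtered; a surviving mate of a broken
#' pair is promoted to singleton.
#'
#' @param reads A read `data.table` (pairs and/or singletons).
#' @param hit Logical vector along rows: did that mate hit the filter?
#' @param category One of `host`, `vector`, `rRNA_tRNA`.
#' @param stringency `"high"` or `"low"`.
#' @return A `data.table` (`read_id`, `mate`, `assigned` category or NA,
#'   `to_singleton` logical) with one row per input row.
#' @export
apply_pair_filter <- function(reads, hit, category = c("host", "vector", "rRNA_tRNA"),
                              stringency = c("high", "low")) {
  category <- match.arg(category)
  stringency <- match.arg(stringency)
  stopifnot(nrow(reads) == length(hit))
  out <- data.table::data.table(read_id = reads$read_id, mate = reads$mate,
                                assigned = NA_character_, to_singleton = FALSE)
  paired <- out$mate %in% c("fwd", "rev")
  if (stringency == "high") {
    pair_hit <- unique(out$read_id[paired][hit[paired]])
    out[paired & out$read_id %in% pair_hit, assigned := category]
    out[!paired & hit, assigned := category]
  } else {
    out[hit, assigned := category]
    # mate survives alone -> singleton
    broken <- out[paired, .(one = sum(is.na(assigned)) == 1L), by = "read_id"]
    broken <- broken$read_id[broken$one]
    out[paired & out$read_id %in% broken & is.na(assigned),
        to_singleton := TRUE]
  }
  out
}

#' Collapse exact-sequence duplicates
#'
#' Emulates 100%-identity clustering: reads with byte-identical sequences
#' collapse to the first occurrence as representative.
#'
#' @param reads A read `data.table`.
#' @return List: `representatives` (subset of `reads`), `cluster_map`
#'   (`data.table` with `rep_id`, `rep_mate`, `member_id`, `member_mate`).
#' @export
dedup_reads <- function(reads) {
  if (nrow(reads) == 0L)
    return(list(representatives = reads,
                cluster_map = data.table::data.table(
                  rep_id = character(), rep_mate = character(),
                  member_id = character(), member_mate = character())))
  first <- !duplicated(reads$sequence)
  rep_idx <- match(reads$sequence, reads$sequence[first])
  reps <- reads[first]
  cluster_map <- data.table::data.table(
    rep_id = reps$read_id[rep_idx], rep_mate = reps$mate[rep_idx],
    member_id = reads$read_id, member_mate = reads$mate)
  list(representatives = reps, cluster_map = cluster_map)
}

#' Repopulate duplicate reads after filtering
#'
#' Only members of clusters whose representative survived filtration are
#' returned; members of filtered clusters inherit the representative's
#' terminal category (handled by the caller via the cluster map).
#'
#' @param cluster_map Cluster map from [dedup_reads()].
#' @param surviving_rep_ids Character vector of representative read ids that
#'   passed the filters (subset of `cluster_map$rep_id`).
#' @return `data.table` of (`member_id`, `member_mate`, `rep_id`) for members
#'   of surviving clusters.
#' @export
repopulate_reads <- function(cluster_map, surviving_rep_ids) {
  unknown <- setdiff(surviving_rep_ids, cluster_map$rep_id)
  if (length(unknown))
    stop("repopulate_reads: unknown representative id(s): ",
         paste(utils::head(unknown, 3), collapse = ", "))
  cluster_map[cluster_map$rep_id %in% surviving_rep_ids,
              c("member_id", "member_mate", "rep_id")]
}

#' Split reads into fixed-size chunks
#'
#' Work is distributed in chunks of 50,000 reads by default; the
#' concatenation of the chunks preserves the input order.
#'
#' @param reads A read `data.table` (or any data.frame-like with rows).
#' @param chunk_size Reads per chunk (>= 1).
#' @return List of row-subsets; all but possibly the last have exactly
#'   `chunk_size` rows.
#' @export
chunk_reads <- function(reads, chunk_size = 50000L) {
  if (chunk_size < 1L) stop("chunk_size must be >= 1")
  n <- nrow(reads)
  if (n == 0L) return(list())
  starts <- seq.int(1L, n, by = chunk_size)
  lapply(starts, function(s) reads[s:min(s + chunk_size - 1L, n), ])
}

#' Disambiguate read ids shared between categories
#'
#' Set algebra used for cross-category accounting: each category keeps only
#' ids exclusive to it; ids present in two or more categories are reported as
#' ambiguous. Output sets are pairwise disjoint.
#'
#' @param category_ids Named list of character vectors (category -> read ids).
#' @return List with one element per input category (exclusive ids) plus
#'   `ambiguous`.
#' @export
disambiguate_categories <- function(category_ids) {
  stopifnot(is.list(category_ids), !is.null(names(category_ids)))
  all_ids <- unlist(category_ids, use.names = FALSE)
  uniq <- lapply(category_ids, unique)
  counts <- table(unlist(uniq, use.names = FALSE))
  ambiguous <- names(counts)[counts >= 2L]
  if (is.null(ambiguous)) ambiguous <- character(0)
  out <- lapply(uniq, function(ids) setdiff(ids, ambiguous))
  c(out, list(ambiguous = ambiguous))
}
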