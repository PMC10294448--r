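# Tiered homology post-processing: a SAM nucleotide tier followed by two
# BLAST-tabular tiers, reduced to a gene-to-read map in which each read id is
# assigned at most once.

#' Default hit-acceptance thresholds
#'
#' @param cigar_coverage_min Minimum fraction of read bases in aligned
#'   (M/=/X) CIGAR operations for the SAM tier. Default 0.90.
#' @param identity_min Minimum percent identity for tabular tiers. Default 85.
#' @param aln_len_fraction_min Minimum alignment length as a percentage of
#'   the (effective) query length. Default 65.
#' @param bitscore_min Minimum bitscore. Default 60.
#' @return List of class `hit_thresholds`.
#' @export
hit_thresholds <- function(cigar_coverage_min = 0.90, identity_min = 85,
                           aln_len_fraction_min = 65, bitscore_min = 60) {
  stopifnot(cigar_coverage_min >= 0, cigar_coverage_min <= 1,
            identity_min >= 0, identity_min <= 100,
            aln_len_fraction_min >= 0, aln_len_fraction_min <= 100,
            bitscore_min >= 0)
  structure(list(cigar_coverage_min = cigar_coverage_min,
                 identity_min = identity_min,
                 aln_len_fraction_min = aln_len_fraction_min,
                 bitscore_min = bitscore_min),
            class = "hit_thresholds")
}

#' Fraction of a read covered by aligned CIGAR operations
#'
#' Counts M, `=` and X operation lengths (I/D/S/H are not reference-aligned)
#' and divides by the read length, capping at 1.
#'
#' @param cigar Character vector of CIGAR strings.
#' @param read_length Integer vector of read lengths (recycled).
#' @return Numeric vector of coverages in `[0, 1]`.
#' @export
cigar_coverage <- function(cigar, read_length) {
  stopifnot(all(read_length >= 1))
  read_length <- rep_len(read_length, length(cigar))
  bad <- !grepl("^([0-9]+[MIDNSHP=X])+$", cigar)
  if (any(bad)) stop("malformed CIGAR string: ", cigar[bad][1])
  aligned <- vapply(cigar, function(cg) {
    lens <- as.numeric(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
    ops <- regmatches(cg, gregexpr("[MIDNSHP=X]", cg))[[1]]
    sum(lens[ops %in% c("M", "=", "X")])
  }, numeric(1), USE.NAMES = FALSE)
  pmin(aligned / read_length, 1)
}

# query length consumed by a CIGAR (M/I/S/=/X), used when SEQ is "*"
cigar_query_length <- function(cigar) {
  vapply(cigar, function(cg) {
    lens <- as.numeric(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
    ops <- regmatches(cg, gregexpr("[MIDNSHP=X]", cg))[[1]]
    sum(lens[ops %in% c("M", "I", "S", "=", "X")])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Read a SAM file into an alignment table
#'
#' Minimal column reader for text SAM as produced by nucleotide aligners:
#' QNAME, FLAG, RNAME, MAPQ, CIGAR, SEQ and the `AS:i:` tag are retained.
#' Secondary/supplementary records are kept as additional candidate matches
#' in file order. The alignment score is the AS tag, falling back to MAPQ
#' when AS is absent.
#'
#' @param path SAM file path (headers optional).
#' @return `data.table` with `read_id`, `mate`, `gene_id`, `cigar`,
#'   `alignment_score`, `mapped`, `read_length`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(lines) == 0L)
    return(data.table::data.table(read_id = character(), mate = character(),
                                  gene_id = character(), cigar = character(),
                                  alignment_score = numeric(),
                                  mapped = logical(),
                                  read_length = integer()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 11L
  if (any(short)) stop("SAM parse error: record with < 11 fields at line ",
                       which(short)[1])
  f <- function(i) vapply(parts, `[[`, "", i)
  flag <- as.integer(f(2))
  qname <- sub("/[12]$", "", f(1))
  mate <- rep("single", length(flag))
  mate[bitwAnd(flag, 64L) > 0L] <- "fwd"
  mate[bitwAnd(flag, 128L) > 0L] <- "rev"
  mapped <- bitwAnd(flag, 4L) == 0L
  cigar <- f(6)
  seq <- f(10)
  read_length <- ifelse(seq != "*", nchar(seq),
                        ifelse(cigar != "*", cigar_query_length(cigar), NA))
  as_tag <- vapply(parts, function(p) {
    tags <- p[-(1:11)]
    hit <- tags[startsWith(tags, "AS:i:")]
    if (length(hit)) as.numeric(sub("^AS:i:", "", hit[1])) else NA_real_
  }, numeric(1))
  score <- ifelse(is.na(as_tag), as.numeric(f(5)), as_tag)
  gene_id <- f(3)
  gene_id[!mapped] <- ""
  data.table::data.table(read_id = qname, mate = mate, gene_id = gene_id,
                         cigar = cigar, alignment_score = score,
                         mapped = mapped,
                         read_length = as.integer(read_length))
}

#' Read a 12-column BLAST tabular (m8 / outfmt 6) report
#'
#' @param path Report path.
#' @return `data.table` with the standard columns `query_id`, `subject_id`,
#'   `percent_identity`, `alignment_length`, `mismatches`, `gap_opens`,
#'   `q_start`, `q_end`, `s_start`, `s_end`, `evalue`, `bitscore`.
#' @export
read_m8 <- function(path) {
  cols <- c("query_id", "subject_id", "percent_identity", "alignment_length",
            "mismatches", "gap_opens", "q_start", "q_end", "s_start", "s_end",
            "evalue", "bitscore")
  dt <- if (file.size(path) == 0)
    data.table::data.table() else
    data.table::fread(path, header = FALSE, sep = "\t")
  if (nrow(dt) == 0L) {
    dt <- data.table::as.data.table(
      stats::setNames(rep(list(character(0)), 12), cols))
    dt[, (3:12) := lapply(.SD, as.numeric), .SDcols = 3:12]
    return(dt)
  }
  if (ncol(dt) < 12L) stop("m8 report must have 12 columns, found ", ncol(dt))
  dt <- dt[, 1:12]
  data.table::setnames(dt, cols)
  dt[, query_id := sub("/[12]$", "", query_id)]
  dt
}

#' Accept or reject a SAM hit
#'
#' A mapped record is accepted when its CIGAR coverage of the read is at
#' least the coverage threshold (default 90%).
#'
#' @param alignment One row (or vectorised columns) with `cigar` and
#'   `mapped`; may be the table from [read_sam()].
#' @param read_length Read length(s) in nt.
#' @param thresholds A [hit_thresholds()] object.
#' @return Logical vector.
#' @export
accept_sam_hit <- function(alignment, read_length, thresholds = hit_thresholds()) {
  if (!all(alignment$mapped)) stop("accept_sam_hit requires mapped records")
  cigar_coverage(alignment$cigar, read_length) >= thresholds$cigar_coverage_min
}

#' Accept or reject a tabular (m8) hit
#'
#' The hit is rejected iff percent identity falls below the identity
#' threshold, OR the alignment length as a percentage of the effective query
#' length falls below the length threshold, OR the bitscore falls below the
#' bitscore threshold. For translated (protein) searches the effective query
#' length is `floor(query_length_nt / 3)` residues.
#'
#' @param hit Row(s) with `percent_identity`, `alignment_length`, `bitscore`.
#' @param query_length_nt Query length(s) in nucleotides.
#' @param translated Is this a translated (protein) search?
#' @param thresholds A [hit_thresholds()] object.
#' @return Logical vector.
#' @export
accept_tabular_hit <- function(hit, query_length_nt, translated = FALSE,
                               thresholds = hit_thresholds()) {
  stopifnot(all(query_length_nt >= 1))
  eff_len <- if (translated) floor(query_length_nt / 3) else query_length_nt
  pct_len <- 100 * hit$alignment_length / eff_len
  !(hit$percent_identity < thresholds$identity_min |
      pct_len < thresholds$aln_len_fraction_min |
      hit$bitscore < thresholds$bitscore_min)
}

#' Best assignment among accepted hits for one read (or pair) id
#'
#' Hits are scanned in report order; a hit becomes the best only when its
#' score strictly exceeds the previous best, so score ties resolve to the
#' earliest maximal-score hit.
#'
#' @param gene_ids Candidate subject/gene ids in report order.
#' @param scores Their scores (alignment score or bitscore).
#' @return List with `gene_id` and `score` of the winning hit.
#' @export
best_assignment <- function(gene_ids, scores) {
  if (length(gene_ids) == 0L) stop("best_assignment: empty hit list")
  i <- which.max(scores)  # first index attaining the maximum
  list(gene_id = gene_ids[[i]], score = scores[[i]])
}

#' Resolve a read pair to a single gene
#'
#' Both mates of a pair are assumed to derive from one transcript: if their
#' best hits disagree, both reads are assigned to the gene with the higher
#' score (fwd wins ties).
#'
#' @param fwd_best,rev_best Lists `(gene_id, score)` from [best_assignment()],
#'   or `NULL` for an unannotated mate.
#' @return The assigned `gene_id`, or `NULL` when neither mate is annotated.
#' @export
resolve_pair <- function(fwd_best, rev_best) {
  if (is.null(fwd_best) && is.null(rev_best)) return(NULL)
  if (is.null(rev_best)) return(fwd_best$gene_id)
  if (is.null(fwd_best)) return(rev_best$gene_id)
  if (fwd_best$gene_id == rev_best$gene_id) return(fwd_best$gene_id)
  if (rev_best$score > fwd_best$score) rev_best$gene_id else fwd_best$gene_id
}

# Per-read best assignment for one SAM tier. Returns data.table
# (read_id, gene_id, n_mates).
sam_tier_assign <- function(sam, read_lengths, thresholds) {
  aln <- sam[sam$mapped]
  if (nrow(aln) == 0L)
    return(data.table::data.table(read_id = character(),
                                  gene_id = character(), n_mates = integer()))
  rl <- aln$read_length
  if (!is.null(read_lengths)) {
    ext <- unname(read_lengths[aln$read_id])
    rl <- ifelse(is.na(rl), ext, rl)
  }
  if (anyNA(rl)) stop("read length unavailable for some SAM records")
  aln <- aln[accept_sam_hit(aln, rl, thresholds)]
  if (nrow(aln) == 0L)
    return(data.table::data.table(read_id = character(),
                                  gene_id = character(), n_mates = integer()))
  per_mate <- aln[, {
    b <- best_assignment(gene_id, alignment_score)
    list(gene_id = b$gene_id, score = b$score)
  }, by = c("read_id", "mate")]
  out <- per_mate[, {
    fb <- if ("fwd" %in% mate) list(gene_id = gene_id[mate == "fwd"],
                                    score = score[mate == "fwd"]) else NULL
    rb <- if ("rev" %in% mate) list(gene_id = gene_id[mate == "rev"],
                                    score = score[mate == "rev"]) else NULL
    g <- if (is.null(fb) && is.null(rb))
      best_assignment(gene_id, score)$gene_id else resolve_pair(fb, rb)
    list(gene_id = g, n_mates = .N)
  }, by = "read_id"]
  out[, c("read_id", "gene_id", "n_mates")]
}

# Per-read best assignment for one m8 tier (pair mates share the query id).
m8_tier_assign <- function(m8, read_lengths, mate_counts, translated,
                           thresholds) {
  if (nrow(m8) == 0L)
    return(data.table::data.table(read_id = character(),
                                  gene_id = character(), n_mates = integer()))
  qlen <- unname(read_lengths[m8$query_id])
  if (anyNA(qlen)) stop("unknown query id(s) in m8 report: ",
                        paste(utils::head(unique(m8$query_id[is.na(qlen)]), 3),
                              collapse = ", "))
  hits <- m8[accept_tabular_hit(m8, qlen, translated, thresholds)]
  if (nrow(hits) == 0L)
    return(data.table::data.table(read_id = character(),
                                  gene_id = character(), n_mates = integer()))
  out <- hits[, {
    b <- best_assignment(subject_id, bitscore)
    list(gene_id = b$gene_id)
  }, by = "query_id"]
  data.table::setnames(out, "query_id", "read_id")
  out[, n_mates := as.integer(mate_counts[read_id])]
  out
}

#' Annotate reads through the tiered cascade
#'
#' Tier 1 consumes a SAM report; reads it annotates are excluded from tier 2;
#' tier 2 (nucleotide m8) acceptances are excluded from tier 3 (translated
#' m8). The resulting gene-to-read map assigns every read id at most once.
#'
#' @param reads A `data.table` with `read_id`, `mate` and `length` (read
#'   length in nt) covering the putative-mRNA reads to annotate.
#' @param tier1_sam,tier2_m8,tier3_m8 Paths to the tier reports (any may be
#'   `NULL` to skip that tier).
#' @param thresholds A [hit_thresholds()] object.
#' @param chunk_size When set, reads are processed in chunks of this many
#'   rows (see [chunk_reads()]) and the per-chunk results combined; because
#'   assignments are per read id, the result is identical to the unchunked
#'   run. Mates of one read id must not straddle a chunk boundary, so
#'   chunking is applied to the table sorted by read id.
#' @return List with `map` (`data.table`: `gene_id`, `read_id`, `tier`,
#'   `n_mates`) and `unannotated` (character vector of read ids).
#' @export
cascade_annotate <- function(reads, tier1_sam = NULL, tier2_m8 = NULL,
                             tier3_m8 = NULL, thresholds = hit_thresholds(),
                             chunk_size = NULL) {
  stopifnot(all(c("read_id", "mate", "length") %in% names(reads)))
  if (!is.null(chunk_size)) {
    ids <- unique(reads$read_id)
    chunks <- chunk_reads(data.table::data.table(read_id = ids), chunk_size)
    parts <- lapply(chunks, function(ch)
      cascade_annotate(reads[reads$read_id %in% ch$read_id],
                       tier1_sam, tier2_m8, tier3_m8, thresholds))
    map <- data.table::rbindlist(lapply(parts, `[[`, "map"))
    data.table::setorderv(map, "read_id")
    unann <- sort(unlist(lapply(parts, `[[`, "unannotated")))
    if (anyDuplicated(map$read_id))
      stop("internal invariant violated: read assigned to more than one gene")
    return(list(map = map, unannotated = unann))
  }
  read_lengths <- tapply(reads$length, reads$read_id, max)
  mate_counts <- table(reads$read_id)
  remaining <- unique(reads$read_id)
  maps <- list()
  tiers <- list(
    list(name = "tier1_nt", path = tier1_sam, kind = "sam"),
    list(name = "tier2_nt", path = tier2_m8, kind = "m8", translated = FALSE),
    list(name = "tier3_prot", path = tier3_m8, kind = "m8", translated = TRUE))
  for (t in tiers) {
    if (is.null(t$path)) next
    asg <- if (t$kind == "sam") {
      sam <- read_sam(t$path)
      a <- sam_tier_assign(sam[sam$read_id %in% remaining & sam$mapped],
                           read_lengths, thresholds)
      # both mates count toward the assigned gene even if only one aligned
      if (nrow(a)) a[, n_mates := as.integer(mate_counts[read_id])]
      a
    } else {
      m8 <- read_m8(t$path)
      m8_tier_assign(m8[m8$query_id %in% remaining], read_lengths,
                     mate_counts, t$translated, thresholds)
    }
    if (nrow(asg)) {
      asg[, tier := t$name]
      maps[[t$name]] <- asg
      remaining <- setdiff(remaining, asg$read_id)
    }
  }
  map <- data.table::rbindlist(maps, use.names = TRUE)
  if (nrow(map) == 0L)
    map <- data.table::data.table(read_id = character(), gene_id = character(),
                                  n_mates = integer(), tier = character())
  if (anyDuplicated(map$read_id))
    stop("internal invariant violated: read assigned to more than one gene")
  data.table::setcolorder(map, c("gene_id", "read_id", "tier", "n_mates"))
  data.table::setorderv(map, "read_id")
  list(map = map, unannotated = sort(remaining))
}

#' Write a gene-to-read map to TSV
#'
#' One row per gene: gene id, tier, number of reads, comma-joined read ids.
#'
#' @param map The `map` component of [cascade_annotate()]'s result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_map <- function(map, path) {
  out <- map[, .(tier = tier[1],
                 n_reads = sum(n_mates),
                 read_ids = paste(read_id, collapse = ",")),
             by = "gene_id"]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

# ---- contig gene models ----------------------------------------------------

#' Build a contig gene index from GFF3 intervals
#'
#' @param gff_path GFF3 file of gene intervals on contigs (1-based inclusive
#'   coordinates); the gene id is taken from the `ID=` attribute.
#' @return `data.table` with `contig_id`, `gene_id`, `start`, `end`, `strand`,
#'   ordered within contig.
#' @export
read_contig_gene_index <- function(gff_path) {
  gr <- rtracklayer::import(gff_path, format = "gff3")
  idx <- data.table::data.table(
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    gene_id = as.character(gr$ID),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)))
  if (anyNA(idx$gene_id)) stop("contig gene intervals need ID attributes")
  if (anyDuplicated(idx$gene_id))
    stop("gene ids in contig index must be unique")
  data.table::setorderv(idx, c("contig_id", "start"))
  idx
}

#' Assign contig-derived reads to discrete gene models
#'
#' Reads previously mapped to contigs are re-aligned against the per-contig
#' gene models; each read is assigned to exactly one gene via the SAM
#' acceptance rule and highest-alignment-score adjudication, and the
#' contig-to-read association is retained alongside.
#'
#' @param contig_read_map `data.table` (`contig_id`, `read_id`) from assembly.
#' @param gene_index Output of [read_contig_gene_index()].
#' @param sam_path SAM of reads aligned against the gene models.
#' @param thresholds A [hit_thresholds()] object.
#' @return `data.table` (`gene_id`, `read_id`, `n_mates`, `contig_id`).
#' @export
map_reads_to_contig_genes <- function(contig_read_map, gene_index, sam_path,
                                      thresholds = hit_thresholds()) {
  sam <- read_sam(sam_path)
  sam <- sam[sam$mapped]
  unknown <- setdiff(sam$gene_id, gene_index$gene_id)
  if (length(unknown))
    stop("gene(s) absent from contig gene index: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  asg <- sam_tier_assign(sam, NULL, thresholds)
  if (nrow(asg) == 0L)
    return(data.table::data.table(gene_id = character(), read_id = character(),
                                  n_mates = integer(), contig_id = character()))
  gi <- gene_index[, c("gene_id", "contig_id")]
  out <- merge(asg, gi, by = "gene_id", all.x = TRUE, sort = FALSE)
  # retain the assembly's contig-to-read association where the aligner
  # assigned the read to a gene on a different contig than the assembler did
  if (!is.null(contig_read_map) && nrow(contig_read_map)) {
    crm <- unique(contig_read_map[, c("read_id", "contig_id")])
    data.table::setnames(crm, "contig_id", "assembled_contig_id")
    out <- merge(out, crm, by = "read_id", all.x = TRUE, sort = FALSE)
    return(out[, c("gene_id", "read_id", "n_mates", "contig_id",
                   "assembled_contig_id")])
  }
  out[, c("gene_id", "read_id", "n_mates", "contig_id")]
}

#' Reference aligner settings for contig gene mapping
#'
#' Recorded as configuration constants for users who run the external
#' nucleotide aligner against contig gene models; the package itself only
#' consumes the resulting SAM.
#' @return Named list (mismatch, gap open, gap extension, clipping penalties).
#' @export
bwa_contig_params <- function() {
  list(B = 40L, O = 60L, E = 10L, L = 50L)
}
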