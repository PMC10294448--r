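# Ground-truthed synthetic inputs: taxonomy dumps, community reads, tiered
# alignment reports, classifier votes and EC predictor outputs, all
# byte-deterministic under a fixed seed. These emulate what the external
# aligners, classifiers and databases would produce, with known truth labels
# for every read.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

random_dna <- function(n, length) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = ""),
    "")
}

#' Generate a balanced synthetic taxonomy
#'
#' Builds root -> one superkingdom -> `n_phyla` phyla -> `n_per_level`
#' children at each of class, order, family, genus and species, and writes
#' NCBI-dialect nodes/names dump files. Deterministic under `seed`.
#'
#' @param n_phyla Number of phyla (>= 1).
#' @param n_per_level Children per node at each lower rank (>= 1).
#' @param dir Output directory for `nodes.dmp` / `names.dmp`.
#' @param seed Integer seed (only affects nothing today; kept for interface
#'   stability of the generator family).
#' @return List with `tree` (a `taxonomy_tree`), `nodes_path`, `names_path`,
#'   and `species` (taxids of the species leaves).
#' @export
make_taxonomy <- function(n_phyla, n_per_level, dir = tempfile("tax"),
                          seed = 1L) {
  stopifnot(n_phyla >= 1, n_per_level >= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  taxid <- 1L; parent <- 1L; rank <- "no_rank"; name <- "root"
  next_id <- 2L
  add <- function(p, r, nm) {
    taxid <<- c(taxid, next_id); parent <<- c(parent, p)
    rank <<- c(rank, r); name <<- c(name, nm)
    id <- next_id; next_id <<- next_id + 1L
    id
  }
  sk <- add(1L, "superkingdom", "Bacteria_synth")
  level_parents <- vapply(seq_len(n_phyla), function(i)
    add(sk, "phylum", paste0("Phylum_", i)), integer(1))
  for (r in c("class", "order", "family", "genus", "species")) {
    level_parents <- unlist(lapply(level_parents, function(p)
      vapply(seq_len(n_per_level), function(i)
        add(p, r, paste0(toupper(substr(r, 1, 1)), substr(r, 2, 3), "_",
                         p, "_", i)), integer(1))))
  }
  nodes_path <- file.path(dir, "nodes.dmp")
  names_path <- file.path(dir, "names.dmp")
  writeLines(paste0(taxid, "\t|\t", parent, "\t|\t", rank, "\t|"), nodes_path)
  writeLines(paste0(taxid, "\t|\t", name, "\t|\t\t|\tscientific name\t|"),
             names_path)
  tree <- load_taxonomy(nodes_path, names_path)
  list(tree = tree, nodes_path = nodes_path, names_path = names_path,
       species = taxid[rank == "species"])
}

#' Specify a synthetic community
#'
#' Defines the planted community: species with taxids, gene repertoires and
#' relative abundances, contaminant fractions, read geometry and the seed.
#' Per-species abundance defaults to a geometric series normalised to 1.
#'
#' @param species_taxids Taxids of the community species (from
#'   [make_taxonomy()]).
#' @param abundances Relative abundances summing to 1 (default geometric).
#' @param genes_per_species Genes per species genome.
#' @param gene_length_range Min/max gene length in bp.
#' @param host_fraction,vector_fraction,rrna_fraction Contaminant read
#'   fractions (must sum to < 1 with room for mRNA).
#' @param low_quality_fraction Fraction of reads planted as low quality.
#' @param read_length Read length in bp.
#' @param n_read_pairs Number of read pairs to simulate.
#' @param paired Paired-end reads?
#' @param substitution_rate Per-base substitution error on mRNA reads.
#' @param ecs_per_gene Range of true EC numbers per gene (1-2 by default).
#' @param seed Integer seed.
#' @return List of class `community_spec`.
#' @export
community_spec <- function(species_taxids,
                           abundances = NULL,
                           genes_per_species = 10L,
                           gene_length_range = c(600L, 1200L),
                           host_fraction = 0.05,
                           vector_fraction = 0.02,
                           rrna_fraction = 0.35,
                           low_quality_fraction = 0.03,
                           read_length = 100L,
                           n_read_pairs = 10000L,
                           paired = TRUE,
                           substitution_rate = 0.005,
                           ecs_per_gene = c(1L, 2L),
                           seed = 1L) {
  k <- length(species_taxids)
  stopifnot(k >= 1)
  if (is.null(abundances)) {
    abundances <- 0.5 ^ seq_len(k)
    abundances <- abundances / sum(abundances)
  }
  if (abs(sum(abundances) - 1) > 1e-9)
    stop("abundances must sum to 1")
  fr <- host_fraction + vector_fraction + rrna_fraction + low_quality_fraction
  if (fr >= 1) stop("contaminant fractions must sum to < 1")
  structure(list(species_taxids = as.integer(species_taxids),
                 abundances = abundances,
                 genes_per_species = genes_per_species,
                 gene_length_range = gene_length_range,
                 host_fraction = host_fraction,
                 vector_fraction = vector_fraction,
                 rrna_fraction = rrna_fraction,
                 low_quality_fraction = low_quality_fraction,
                 read_length = read_length,
                 n_read_pairs = n_read_pairs,
                 paired = paired,
                 substitution_rate = substitution_rate,
                 ecs_per_gene = ecs_per_gene,
                 seed = seed),
            class = "community_spec")
}

# Gene catalogue for a community: ids carry a synthetic accession so the
# accession->taxid lookup works. True ECs drawn from a small EC universe.
make_gene_catalogue <- function(spec) {
  with_seed(spec$seed + 101L, {
    k <- length(spec$species_taxids)
    n_genes <- k * spec$genes_per_species
    len <- sample(spec$gene_length_range[1]:spec$gene_length_range[2],
                  n_genes, replace = TRUE)
    ec_universe <- sprintf("%d.%d.%d.%d",
                           sample(1:6, 40, TRUE), sample(1:20, 40, TRUE),
                           sample(1:30, 40, TRUE), sample(1:99, 40, TRUE))
    ec_universe <- unique(ec_universe)
    genes <- data.table::data.table(
      gene_id = sprintf("SYNACC%04d.1", seq_len(n_genes)),
      taxid = rep(spec$species_taxids, each = spec$genes_per_species),
      length_bp = len,
      sequence = random_dna(n_genes, 1L))  # placeholder, filled below
    genes$sequence <- vapply(len, function(l)
      paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""), "")
    n_ec <- sample(spec$ecs_per_gene[1]:spec$ecs_per_gene[2], n_genes,
                   replace = TRUE)
    genes$ecs <- lapply(n_ec, function(m) sample(ec_universe, m))
    genes
  })
}

#' Generate community reads with ground truth
#'
#' Draws each read pair's true category (host / vector / rRNA_tRNA /
#' low_quality / mRNA) from the spec's fractions; mRNA pairs come from a
#' species (by abundance) and one of its genes, with uniform substitution
#' errors. Writes paired (or single-end) FASTQ plus a truth table.
#'
#' @param spec A [community_spec()].
#' @param dir Output directory.
#' @return List: `fastq_fwd`, `fastq_rev` (NULL if single-end), `truth`
#'   (`data.table`: `read_id`, `category`, `gene_id`, `taxid`), `genes`
#'   (gene catalogue), `accession_map_path`, and per-mate filter hit lists
#'   `hit_lists` (paths keyed by category).
#' @export
make_reads <- function(spec, dir = tempfile("reads")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genes <- make_gene_catalogue(spec)
  with_seed(spec$seed + 202L, {
    n <- spec$n_read_pairs
    cats <- c("host", "vector", "rRNA_tRNA", "low_quality", "mRNA")
    probs <- c(spec$host_fraction, spec$vector_fraction, spec$rrna_fraction,
               spec$low_quality_fraction,
               1 - spec$host_fraction - spec$vector_fraction -
                 spec$rrna_fraction - spec$low_quality_fraction)
    category <- sample(cats, n, replace = TRUE, prob = probs)
    read_id <- sprintf("read%06d", seq_len(n))
    true_gene <- rep(NA_character_, n)
    true_taxid <- rep(0L, n)
    is_mrna <- category == "mRNA"
    gene_row <- rep(NA_integer_, n)
    if (any(is_mrna)) {
      sp <- sample(seq_along(spec$species_taxids), sum(is_mrna),
                   replace = TRUE, prob = spec$abundances)
      gidx <- vapply(sp, function(s)
        sample(which(genes$taxid == spec$species_taxids[s]), 1L), integer(1))
      gene_row[is_mrna] <- gidx
      true_gene[is_mrna] <- genes$gene_id[gidx]
      true_taxid[is_mrna] <- genes$taxid[gidx]
    }
    rl <- spec$read_length
    gene_seqs <- genes$sequence
    gene_lens <- genes$length_bp
    draw_seq <- function(i) {
      if (!is_mrna[i]) return(paste(sample(c("A", "C", "G", "T"), rl,
                                           replace = TRUE), collapse = ""))
      j <- gene_row[i]
      start <- sample(max(1L, gene_lens[j] - rl + 1L), 1L)
      s <- substr(gene_seqs[j], start, min(start + rl - 1L, gene_lens[j]))
      chars <- strsplit(s, "")[[1]]
      err <- stats::runif(length(chars)) < spec$substitution_rate
      chars[err] <- sample(c("A", "C", "G", "T"), sum(err), replace = TRUE)
      paste(chars, collapse = "")
    }
    qual_for <- function(cat, len) {
      q <- if (cat == "low_quality") sample(5:15, len, TRUE)
           else sample(30:40, len, TRUE)
      intToUtf8(q + 33L)
    }
    seq_fwd <- vapply(seq_len(n), draw_seq, "")
    truth <- data.table::data.table(read_id = read_id, category = category,
                                    gene_id = true_gene, taxid = true_taxid)
    if (spec$paired) {
      seq_rev <- vapply(seq_len(n), draw_seq, "")
      qual_fwd <- vapply(seq_len(n), function(i)
        qual_for(category[i], nchar(seq_fwd[i])), "")
      qual_rev <- vapply(seq_len(n), function(i)
        qual_for(category[i], nchar(seq_rev[i])), "")
      fwd <- read_table(read_id, "fwd", seq_fwd, qual_fwd)
      rev <- read_table(read_id, "rev", seq_rev, qual_rev)
      fq1 <- file.path(dir, "reads_1.fastq")
      fq2 <- file.path(dir, "reads_2.fastq")
      write_fastq(fwd, fq1); write_fastq(rev, fq2)
      mates <- data.table::rbindlist(list(fwd, rev))
    } else {
      qual_fwd <- vapply(seq_len(n), function(i)
        qual_for(category[i], nchar(seq_fwd[i])), "")
      fwd <- read_table(read_id, "single", seq_fwd, qual_fwd)
      fq1 <- file.path(dir, "reads.fastq")
      write_fastq(fwd, fq1)
      fq2 <- NULL
      mates <- fwd
    }
    # per-mate filter hit lists standing in for the filter aligners' outputs
    hit_lists <- list()
    for (cat in c("low_quality", "host", "vector", "rRNA_tRNA")) {
      ids <- truth$read_id[truth$category == cat]
      hits <- mates[mates$read_id %in% ids, c("read_id", "mate")]
      p <- file.path(dir, paste0(cat, "_hits.tsv"))
      data.table::fwrite(hits, p, sep = "\t", col.names = FALSE)
      hit_lists[[cat]] <- p
    }
    acc_path <- file.path(dir, "accession2taxid.tsv")
    bare <- sub("\\.\\d+$", "", genes$gene_id)
    data.table::fwrite(data.table::data.table(
      accession = bare, accession.version = genes$gene_id,
      taxid = genes$taxid, gi = seq_len(nrow(genes))),
      acc_path, sep = "\t")
    list(fastq_fwd = fq1, fastq_rev = fq2, truth = truth, genes = genes,
         accession_map_path = acc_path, hit_lists = hit_lists, dir = dir)
  })
}

#' Generate tiered alignment reports from truth
#'
#' Each true-mRNA read receives a correct above-threshold hit at a random
#' tier with probability `1 - miss_rate`; spurious hits (below-threshold or
#' wrong-gene with lower score) are injected at `spurious_rate`. With both
#' rates zero, the cascade's acceptance rules recover the truth exactly.
#'
#' @param reads Output of [make_reads()].
#' @param spec The [community_spec()] used to build `reads`.
#' @param miss_rate Probability that a true mRNA read gets no acceptable hit.
#' @param spurious_rate Probability of injecting a decoy hit for a read.
#' @param dir Output directory.
#' @param seed Integer seed.
#' @return List with `tier1_sam`, `tier2_m8`, `tier3_m8` paths.
#' @export
make_alignment_reports <- function(reads, spec, miss_rate = 0,
                                   spurious_rate = 0,
                                   dir = reads$dir, seed = spec$seed + 303L) {
  stopifnot(miss_rate >= 0, miss_rate < 1, spurious_rate >= 0,
            spurious_rate < 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- reads$truth
  genes <- reads$genes
  rl <- spec$read_length
  with_seed(seed, {
    mrna <- truth[truth$category == "mRNA"]
    n <- nrow(mrna)
    hit_ok <- stats::runif(n) >= miss_rate
    tier <- sample(1:3, n, replace = TRUE)
    sam_lines <- character(0)
    m8_2 <- character(0)
    m8_3 <- character(0)
    decoy_genes <- genes$gene_id
    for (i in seq_len(n)) {
      id <- mrna$read_id[i]; g <- mrna$gene_id[i]
      if (hit_ok[i]) {
        if (tier[i] == 1L) {
          # both mates aligned, full-length match, high AS
          sam_lines <- c(sam_lines, sprintf(
            "%s\t%d\t%s\t1\t60\t%dM\t*\t0\t0\t%s\t%s\tAS:i:%d",
            id, 99L, g, rl, strrep("A", rl), strrep("I", rl), rl))
          if (spec$paired)
            sam_lines <- c(sam_lines, sprintf(
              "%s\t%d\t%s\t1\t60\t%dM\t*\t0\t0\t%s\t%s\tAS:i:%d",
              id, 147L, g, rl, strrep("A", rl), strrep("I", rl), rl - 1L))
        } else if (tier[i] == 2L) {
          m8_2 <- c(m8_2, sprintf(
            "%s\t%s\t%.1f\t%d\t1\t0\t1\t%d\t1\t%d\t%.1e\t%.1f",
            id, g, 98.0, rl, rl, rl, 1e-30, 180.0))
        } else {
          pl <- floor(rl / 3)
          m8_3 <- c(m8_3, sprintf(
            "%s\t%s\t%.1f\t%d\t1\t0\t1\t%d\t1\t%d\t%.1e\t%.1f",
            id, g, 95.0, pl, pl, pl, 1e-20, 120.0))
        }
      }
      if (stats::runif(1) < spurious_rate) {
        dg <- sample(decoy_genes, 1L)
        # below-threshold decoy: fails identity and bitscore cutoffs
        m8_2 <- c(m8_2, sprintf(
          "%s\t%s\t%.1f\t%d\t10\t2\t1\t%d\t1\t%d\t%.1e\t%.1f",
          id, dg, 70.0, floor(rl / 2), floor(rl / 2), floor(rl / 2),
          1e-3, 40.0))
      }
    }
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                sprintf("@SQ\tSN:%s\tLN:%d", genes$gene_id, genes$length_bp))
    t1 <- file.path(dir, "tier1.sam")
    t2 <- file.path(dir, "tier2.m8")
    t3 <- file.path(dir, "tier3.m8")
    writeLines(c(header, sam_lines), t1)
    writeLines(m8_2, t2)
    writeLines(m8_3, t3)
    list(tier1_sam = t1, tier2_m8 = t2, tier3_m8 = t3)
  })
}

#' Generate classifier vote files from truth
#'
#' Each source votes the true species taxid with its stated accuracy;
#' otherwise it votes a confusable congeneric sibling species (or is
#' unclassified when no sibling exists). Votes are emitted for putative-mRNA
#' reads; non-mRNA reads are not voted on.
#'
#' @param reads Output of [make_reads()].
#' @param tree `taxonomy_tree` containing the community species.
#' @param accuracy Named vector of per-source accuracies in `[0, 1]` for
#'   `gene_lookup`, `kaiju`, `centrifuge`.
#' @param dir Output directory.
#' @param seed Integer seed.
#' @return Named list of vote file paths per source.
#' @export
make_classifier_votes <- function(reads, tree,
                                  accuracy = c(gene_lookup = 1, kaiju = 1,
                                               centrifuge = 1),
                                  dir = reads$dir, seed = 404L) {
  stopifnot(all(accuracy >= 0), all(accuracy <= 1))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- reads$truth[reads$truth$category == "mRNA"]
  sibling_of <- function(taxid) {
    g <- ancestor_at_rank(tree, taxid, "genus")
    if (is.na(g)) return(0L)
    sibs <- tree$taxid[tree$parent == g & tree$taxid != taxid &
                         tree$rank == "species"]
    if (length(sibs) == 0L) return(0L)
    sibs[1]
  }
  with_seed(seed, {
    paths <- list()
    for (src in names(accuracy)) {
      correct <- stats::runif(nrow(truth)) < accuracy[[src]]
      voted <- ifelse(correct, truth$taxid,
                      vapply(truth$taxid, sibling_of, integer(1)))
      flag <- ifelse(voted == 0L, "U", "C")
      p <- file.path(dir, paste0(src, "_votes.tsv"))
      data.table::fwrite(data.table::data.table(flag, truth$read_id, voted),
                         p, sep = "\t", col.names = FALSE)
      paths[[src]] <- p
    }
    paths
  })
}

#' Generate EC predictor fixtures from truth
#'
#' Emits each gene's true EC(s) per source with the stated sensitivity.
#' PRIAM probabilities and DIAMOND e-values are drawn on both sides of the
#' stringency cutoffs (unless fixed) so both report modes are exercised.
#' The pair database covers all true co-occurring pairs.
#'
#' @param reads Output of [make_reads()].
#' @param detect_sens,priam_sens,diamond_sens Per-source sensitivities.
#' @param priam_prob_range,diamond_log10e_range Sampling ranges; pass equal
#'   bounds to fix a value.
#' @param dir Output directory.
#' @param seed Integer seed.
#' @return List: `detect_path`, `priam_path`, `diamond_ec` (a `data.table`
#'   ready for [merge_predictions()]), `diamond_path`, `pair_db_path`.
#' @export
make_ec_fixture <- function(reads, detect_sens = 1, priam_sens = 1,
                            diamond_sens = 1,
                            priam_prob_range = c(0.3, 0.99),
                            diamond_log10e_range = c(-20, -3),
                            dir = reads$dir, seed = 505L) {
  genes <- reads$genes
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(seed, {
    rows <- genes[, .(ec = unlist(ecs)), by = "gene_id"]
    emit <- function(sens) rows[stats::runif(nrow(rows)) < sens]
    det <- emit(detect_sens)
    det[, probability := round(stats::runif(.N, 0.85, 1), 4)]
    pri <- emit(priam_sens)
    pri[, probability := round(stats::runif(.N, priam_prob_range[1],
                                            priam_prob_range[2]), 4)]
    dia <- emit(diamond_sens)
    dia[, evalue := 10 ^ stats::runif(.N, diamond_log10e_range[1],
                                      diamond_log10e_range[2])]
    detect_path <- file.path(dir, "detect_predictions.tsv")
    priam_path <- file.path(dir, "priam_predictions.tsv")
    diamond_path <- file.path(dir, "diamond_ec.tsv")
    data.table::fwrite(det[, .(target_id = gene_id, ec, probability)],
                       detect_path, sep = "\t")
    data.table::fwrite(pri[, .(target_id = gene_id, ec, probability)],
                       priam_path, sep = "\t")
    diamond_ec <- dia[, .(target_id = gene_id, ec, evalue)]
    data.table::fwrite(diamond_ec, diamond_path, sep = "\t")
    # pair DB covering all true co-occurring pairs
    pairs <- genes[lengths(ecs) >= 2L,
                   .(a = vapply(ecs, `[[`, "", 1), b = vapply(ecs, `[[`, "", 2))]
    if (nrow(pairs) == 0L)
      pairs <- data.table::data.table(a = "1.1.1.1", b = "2.2.2.2")
    pair_db_path <- file.path(dir, "ec_pairs.tsv")
    data.table::fwrite(unique(pairs), pair_db_path, sep = "\t",
                       col.names = FALSE)
    # simple superpathway map: ECs binned by top-level class
    sp_path <- file.path(dir, "ec_superpathways.tsv")
    all_ec <- unique(rows$ec)
    data.table::fwrite(data.table::data.table(
      ec = all_ec,
      superpathway = paste0("Superpathway_", sub("\\..*$", "", all_ec))),
      sp_path, sep = "\t")
    list(detect_path = detect_path, priam_path = priam_path,
         diamond_path = diamond_path, diamond_ec = diamond_ec,
         pair_db_path = pair_db_path, superpathway_path = sp_path)
  })
}

#' Generate a complete synthetic sample directory
#'
#' Convenience wrapper running all generators and writing a pipeline
#' configuration file, so `run_pipeline()` (or the CLI `run` subcommand) can
#' consume the directory directly.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param n_species Number of community species.
#' @param n_read_pairs Number of read pairs.
#' @param miss_rate,spurious_rate Alignment noise (see
#'   [make_alignment_reports()]).
#' @param classifier_accuracy Named accuracies (see
#'   [make_classifier_votes()]).
#' @param ... Further arguments to [community_spec()].
#' @return List with `config_path`, `spec`, `reads`, `tree` and all fixture
#'   paths.
#' @export
simulate_sample <- function(dir, seed = 1L, n_species = 5L,
                            n_read_pairs = 10000L, miss_rate = 0,
                            spurious_rate = 0,
                            classifier_accuracy = c(gene_lookup = 1,
                                                    kaiju = 1,
                                                    centrifuge = 1), ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tax <- make_taxonomy(2L, 3L, dir = file.path(dir, "taxonomy"), seed = seed)
  species <- with_seed(seed + 7L,
                       sample(tax$species, n_species))
  spec <- community_spec(species_taxids = species,
                         n_read_pairs = n_read_pairs, seed = seed, ...)
  reads <- make_reads(spec, dir = file.path(dir, "sample"))
  aln <- make_alignment_reports(reads, spec, miss_rate = miss_rate,
                                spurious_rate = spurious_rate)
  votes <- make_classifier_votes(reads, tax$tree,
                                 accuracy = classifier_accuracy,
                                 seed = seed + 404L)
  ecs <- make_ec_fixture(reads, seed = seed + 505L)
  truth_path <- file.path(dir, "sample", "truth.tsv")
  data.table::fwrite(reads$truth, truth_path, sep = "\t")
  cfg <- c(
    paste0("fastq_fwd=", reads$fastq_fwd),
    if (!is.null(reads$fastq_rev)) paste0("fastq_rev=", reads$fastq_rev),
    paste0("lowq_hits=", reads$hit_lists$low_quality),
    paste0("host_hits=", reads$hit_lists$host),
    paste0("vector_hits=", reads$hit_lists$vector),
    paste0("rrna_hits=", reads$hit_lists$rRNA_tRNA),
    paste0("tier1_sam=", aln$tier1_sam),
    paste0("tier2_m8=", aln$tier2_m8),
    paste0("tier3_m8=", aln$tier3_m8),
    paste0("nodes_dmp=", tax$nodes_path),
    paste0("names_dmp=", tax$names_path),
    paste0("accession_map=", reads$accession_map_path),
    paste0("kaiju_votes=", votes$kaiju),
    paste0("centrifuge_votes=", votes$centrifuge),
    paste0("detect_predictions=", ecs$detect_path),
    paste0("priam_predictions=", ecs$priam_path),
    paste0("diamond_ec=", ecs$diamond_path),
    paste0("ec_pair_db=", ecs$pair_db_path),
    paste0("ec_superpathways=", ecs$superpathway_path),
    paste0("gene_lengths=", {
      p <- file.path(dir, "sample", "gene_lengths.tsv")
      data.table::fwrite(reads$genes[, .(gene_id, length_bp)], p, sep = "\t",
                         col.names = FALSE)
      p
    }))
  config_path <- file.path(dir, "config.ini")
  writeLines(cfg, config_path)
  list(config_path = config_path, spec = spec, reads = reads, tree = tax$tree,
       taxonomy = tax, alignments = aln, votes = votes, ec = ecs,
       truth_path = truth_path)
}
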