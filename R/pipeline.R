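# Orchestration: configuration parsing with the printed default thresholds,
# stage sequencing with checkpoint files, and the single-sample run contract.

CONFIG_DEFAULTS <- list(
  filter_stringency = "high",
  cigar_coverage_min = 0.90,
  identity_min = 85,
  aln_len_fraction_min = 65,
  bitscore_min = 60,
  ec_evalue_low = 1e-5,
  ec_evalue_high = 1e-10,
  priam_prob_min = 0.5,
  weight_gene_lookup = 0.6,
  weight_kaiju = 0.2,
  weight_centrifuge = 0.2,
  taxa_cutoff = 0.01,
  heatmap_top_n = 20L,
  chunk_size = 50000L,
  keep_interim = "keep")

CONFIG_PATHS <- c("fastq_fwd", "fastq_rev", "lowq_hits", "host_hits",
                  "vector_hits", "rrna_hits", "tier1_sam", "tier2_m8",
                  "tier3_m8", "nodes_dmp", "names_dmp", "accession_map",
                  "kaiju_votes", "centrifuge_votes", "detect_predictions",
                  "priam_predictions", "diamond_ec", "ec_pair_db",
                  "ec_superpathways", "gene_lengths", "contig_gff",
                  "contig_read_map")

#' Default pipeline configuration
#'
#' Exposes the method's printed defaults: 90% CIGAR coverage, 85% identity,
#' 65% alignment-length fraction, bitscore 60, EC e-value cutoffs 1e-5 (low)
#' and 1e-10 (high), PRIAM probability 0.5, consensus weights 0.6/0.2/0.2,
#' 1% taxon rollup cutoff, top-20 heatmap taxa and 50,000-read chunks.
#'
#' @return Named list of configuration values (class `pipeline_config`).
#' @export
default_config <- function() {
  cfg <- CONFIG_DEFAULTS
  cfg$bwa_contig_params <- bwa_contig_params()
  structure(cfg, class = "pipeline_config")
}

#' Parse and validate a pipeline configuration file
#'
#' Keyed text (`key=value`, `#` comments). Absent keys take the defaults of
#' [default_config()]; unknown keys warn; out-of-range values error naming
#' the field.
#'
#' @param path Configuration file path, or `NULL` for pure defaults.
#' @return A validated `pipeline_config`.
#' @export
validate_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) < 2L) stop("malformed config line: ", ln)
      key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
      if (key %in% names(CONFIG_DEFAULTS)) {
        proto <- CONFIG_DEFAULTS[[key]]
        cfg[[key]] <- if (is.numeric(proto)) as.numeric(val) else val
      } else if (key %in% CONFIG_PATHS) {
        cfg[[key]] <- val
      } else {
        warning("unknown configuration key: ", key)
      }
    }
  }
  check_range <- function(field, lo, hi) {
    v <- cfg[[field]]
    if (!is.numeric(v) || is.na(v) || v < lo || v > hi)
      stop("configuration field out of range: ", field,
           " (must be in [", lo, ", ", hi, "])")
  }
  check_range("cigar_coverage_min", 0, 1)
  check_range("identity_min", 0, 100)
  check_range("aln_len_fraction_min", 0, 100)
  check_range("bitscore_min", 0, Inf)
  check_range("ec_evalue_low", 0, 1)
  check_range("ec_evalue_high", 0, 1)
  check_range("priam_prob_min", 0, 1)
  check_range("taxa_cutoff", 0, 1)
  check_range("chunk_size", 1, Inf)
  check_range("heatmap_top_n", 1, Inf)
  if (!cfg$filter_stringency %in% c("high", "low"))
    stop("configuration field out of range: filter_stringency")
  if (!cfg$keep_interim %in% c("keep", "compress", "delete"))
    stop("configuration field out of range: keep_interim")
  w <- c(cfg$weight_gene_lookup, cfg$weight_kaiju, cfg$weight_centrifuge)
  if (any(w <= 0) || abs(sum(w) - 1) > 1e-9)
    stop("configuration field out of range: consensus weights must be ",
         "positive and sum to 1")
  cfg
}

read_hit_list <- function(path) {
  if (is.null(path) || !file.exists(path))
    return(data.table::data.table(read_id = character(), mate = character()))
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = "character")
  if (nrow(dt) == 0L)
    return(data.table::data.table(read_id = character(), mate = character()))
  if (ncol(dt) == 1L) dt[, V2 := "single"]
  data.table::setnames(dt, 1:2, c("read_id", "mate"))
  dt[, c("read_id", "mate")]
}

checkpoint_path <- function(out_dir, stage) {
  file.path(out_dir, "checkpoints", paste0(stage, ".json"))
}

checkpoint_ok <- function(out_dir, stage) {
  p <- checkpoint_path(out_dir, stage)
  if (!file.exists(p)) return(FALSE)
  info <- tryCatch(jsonlite::read_json(p, simplifyVector = TRUE),
                   error = function(e) NULL)
  if (is.null(info) || !identical(info$stage, stage)) return(FALSE)
  all(vapply(unlist(info$outputs), file.exists, logical(1)))
}

checkpoint_write <- function(out_dir, stage, outputs) {
  p <- checkpoint_path(out_dir, stage)
  dir.create(dirname(p), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(stage = stage, outputs = as.list(outputs),
                            time = format(Sys.time())),
                       p, auto_unbox = TRUE)
}

pipeline_log <- function(out_dir, ...) {
  msg <- paste0(...)
  message(msg)
  cat(msg, "\n", file = file.path(out_dir, "run.log"), append = TRUE)
}

# Stage 1: build the ledger through quality, dedup, host/vector/rRNA filters
# with orphan promotion and duplicate repopulation.
stage_ledger <- function(cfg, out_dir) {
  fwd <- read_fastq(cfg$fastq_fwd, mate = if (is.null(cfg$fastq_rev))
    "single" else "fwd")
  reads <- if (!is.null(cfg$fastq_rev)) {
    rev <- read_fastq(cfg$fastq_rev, mate = "rev")
    data.table::rbindlist(list(fwd, rev))
  } else fwd
  ledger <- ledger_init(reads)
  key <- function(dt) paste(dt$read_id, dt$mate)
  # quality filter (per-mate): failing mates are terminal low_quality;
  # orphaned survivors continue as singletons. The ledger is keyed by the
  # original mate, so the original mate travels alongside the current one.
  lowq <- read_hit_list(cfg$lowq_hits)
  is_lowq <- key(reads) %in% key(lowq)
  ledger_record(ledger, reads$read_id[is_lowq], reads$mate[is_lowq],
                "low_quality")
  active <- reads[!is_lowq]
  active[, orig_mate := mate]
  paired <- active$mate %in% c("fwd", "rev")
  if (any(paired)) {
    pr <- promote_orphans(active[paired], rep(TRUE, sum(paired)))
    orphan <- setdiff(active$read_id[paired],
                      pr$pairs$read_id)  # mate lost to quality
    sel <- paired & active$read_id %in% orphan
    ledger_record(ledger, active$read_id[sel], active$mate[sel], "singleton")
    active$mate[sel] <- "single"
  }
  # lookup: current (read, mate) key -> original mate for ledger records
  m2o <- stats::setNames(active$orig_mate, key(active))
  rec <- function(ids, cur_mates, category) {
    ledger_record(ledger, ids, unname(m2o[paste(ids, cur_mates)]), category)
  }
  # dedup before the expensive filters; repopulate afterwards
  dd <- dedup_reads(active)
  reps <- dd$representatives
  reps[, rk := paste(read_id, mate)]  # stable id; survives mate relabels
  cm <- dd$cluster_map
  cm[, rep_key := paste(rep_id, rep_mate)]
  cm[, member_key := paste(member_id, member_mate)]
  member_orig_key <- paste(cm$member_id, m2o[cm$member_key])
  filtered_rk <- character(0); filtered_cat <- character(0)
  for (stage in list(c("host_hits", "host"), c("vector_hits", "vector"),
                     c("rrna_hits", "rRNA_tRNA"))) {
    hits <- read_hit_list(cfg[[stage[1]]])
    # a representative hits if any member of its cluster is on the hit list
    # (hit lists name reads by their original mate)
    member_hit <- member_orig_key %in% key(hits)
    rep_hit_rks <- unique(cm$rep_key[member_hit])
    cur_hit <- reps$rk %in% rep_hit_rks
    res <- apply_pair_filter(reps, cur_hit, stage[2], cfg$filter_stringency)
    out <- !is.na(res$assigned)
    filtered_rk <- c(filtered_rk, reps$rk[out])
    filtered_cat <- c(filtered_cat, rep(stage[2], sum(out)))
    reps$mate[res$to_singleton] <- "single"
    reps <- reps[!out]
  }
  # repopulate: members inherit their representative's fate
  filt_map <- stats::setNames(filtered_cat, filtered_rk)
  cm[, fate := filt_map[rep_key]]
  for (category in FILTER_CATEGORIES) {
    m <- cm[!is.na(fate) & fate == category]
    rec(m$member_id, m$member_mate, category)
  }
  # survivors (all duplicates of surviving representatives) are putative mRNA
  surv <- cm[rep_key %in% reps$rk]
  rec(surv$member_id, surv$member_mate, "putative_mRNA")
  putative <- active[key(active) %in% surv$member_key]
  # mates demoted to singleton during filtering follow their representative
  mate_now <- stats::setNames(reps$mate, reps$rk)
  rep_of <- stats::setNames(cm$rep_key, cm$member_key)
  new_mate <- mate_now[rep_of[key(putative)]]
  putative$mate <- ifelse(is.na(new_mate), putative$mate, new_mate)
  putative[, orig_mate := NULL]
  list(ledger = ledger, putative = putative)
}

#' Run the full post-processing pipeline on one sample
#'
#' Stages run in order (ledger, gene annotation, enzyme annotation,
#' consensus, reports); each stage writes a checkpoint under
#' `out_dir/checkpoints/` and a rerun with `resume = TRUE` skips completed
#' stages whose outputs still exist. One sample per invocation.
#'
#' @param config A `pipeline_config` from [validate_config()], with input
#'   paths set.
#' @param out_dir Output directory for all reports.
#' @param resume Skip stages with valid checkpoints?
#' @return Named list of report paths, invisibly; a `summary` element holds
#'   the read-summary fields.
#' @export
run_pipeline <- function(config, out_dir, resume = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  state_dir <- file.path(out_dir, "interim")
  dir.create(state_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list(
    ledger = file.path(out_dir, "read_ledger.tsv"),
    gene_map = file.path(out_dir, "gene_map.tsv"),
    ec_low = file.path(out_dir, "ec_report_low.tsv"),
    ec_high = file.path(out_dir, "ec_report_high.tsv"),
    consensus = file.path(out_dir, "taxonomic_consensus.tsv"),
    taxa = file.path(out_dir, "taxa_table.tsv"),
    rollup = file.path(out_dir, "taxa_rollup.tsv"),
    expression = file.path(out_dir, "gene_expression.tsv"),
    cytoscape = file.path(out_dir, "cytoscape_ec.tsv"),
    heatmap = file.path(out_dir, "EC_coverage.csv"),
    summary_tsv = file.path(out_dir, "read_summary.tsv"),
    quality = file.path(out_dir, "quality_histogram.tsv"))

  run_stage <- function(stage, paths, fun) {
    if (resume && checkpoint_ok(out_dir, stage)) {
      pipeline_log(out_dir, "[", stage, "] checkpoint found, skipping")
      return(FALSE)
    }
    pipeline_log(out_dir, "[", stage, "] running")
    ok <- tryCatch({fun(); TRUE}, error = function(e) {
      pipeline_log(out_dir, "[", stage, "] FAILED: ", conditionMessage(e))
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    checkpoint_write(out_dir, stage, paths)
    TRUE
  }

  env <- new.env()
  st_file <- function(name) file.path(state_dir, paste0(name, ".rds.tsv"))

  run_stage("ledger", c(outputs$ledger), function() {
    st1 <- stage_ledger(config, out_dir)
    env$st1 <- st1
    ledger_snapshot <- data.table::copy(st1$ledger)
    # putative-mRNA reads are not terminal yet; placeholder for export
    data.table::fwrite(ledger_snapshot, file.path(state_dir, "ledger_raw.tsv"),
                       sep = "\t")
    data.table::fwrite(st1$putative, file.path(state_dir, "putative.tsv"),
                       sep = "\t")
    data.table::fwrite(ledger_snapshot, outputs$ledger, sep = "\t")
  })
  if (is.null(env$st1)) {
    led <- data.table::fread(file.path(state_dir, "ledger_raw.tsv"),
                             colClasses = "character")
    led[led$terminal == "", terminal := NA_character_]
    data.table::setkeyv(led, c("read_id", "mate"))
    env$st1 <- list(ledger = led,
                    putative = data.table::fread(
                      file.path(state_dir, "putative.tsv"),
                      colClasses = "character"))
  }

  run_stage("gene_annotation", c(outputs$gene_map), function() {
    putative <- env$st1$putative
    reads <- data.table::data.table(read_id = putative$read_id,
                                    mate = putative$mate,
                                    length = nchar(putative$sequence))
    thr <- hit_thresholds(config$cigar_coverage_min, config$identity_min,
                          config$aln_len_fraction_min, config$bitscore_min)
    res <- cascade_annotate(reads, config$tier1_sam, config$tier2_m8,
                            config$tier3_m8, thr)
    env$gene <- res
    data.table::fwrite(res$map, file.path(state_dir, "gene_assignments.tsv"),
                       sep = "\t")
    write_gene_map(res$map, outputs$gene_map)
  })
  if (is.null(env$gene)) {
    map <- data.table::fread(file.path(state_dir, "gene_assignments.tsv"))
    env$gene <- list(map = map,
                     unannotated = setdiff(env$st1$putative$read_id,
                                           map$read_id))
  }

  run_stage("enzyme_annotation", c(outputs$ec_low, outputs$ec_high),
            function() {
    detect <- read_ec_predictions(config$detect_predictions)
    priam <- read_ec_predictions(config$priam_predictions)
    diamond <- data.table::fread(config$diamond_ec, header = "auto")
    data.table::setnames(diamond, 1:3, c("target_id", "ec", "evalue"))
    pair_db <- load_ec_pair_db(config$ec_pair_db)
    # restrict to genes the sample actually expresses
    expressed <- unique(env$gene$map$gene_id)
    env$ec <- ec_reports(detect[detect$target_id %in% expressed],
                         priam[priam$target_id %in% expressed],
                         diamond[diamond$target_id %in% expressed],
                         pair_db, outputs$ec_low, outputs$ec_high)
  })
  if (is.null(env$ec)) {
    low <- data.table::fread(outputs$ec_low)
    high <- data.table::fread(outputs$ec_high)
    env$ec <- list(low = low, high = high,
                   n_unique_ec = c(low = length(unique(low$ec)),
                                   high = length(unique(high$ec))))
  }

  run_stage("consensus", c(outputs$consensus, outputs$taxa), function() {
    tree <- load_taxonomy(config$nodes_dmp, config$names_dmp)
    acc <- load_accession_map(config$accession_map)
    gv <- gene_vote(env$gene$map$read_id, env$gene$map$gene_id, acc)
    kj <- read_classifier_votes(config$kaiju_votes, "kaiju")
    cf <- read_classifier_votes(config$centrifuge_votes, "centrifuge")
    putative_ids <- unique(env$st1$putative$read_id)
    votes <- data.table::rbindlist(list(gv, kj, cf))
    votes <- votes[votes$read_id %in% putative_ids]
    cons <- weighted_consensus(votes, tree,
                               consensus_weights(config$weight_gene_lookup,
                                                 config$weight_kaiju,
                                                 config$weight_centrifuge))
    # putative reads with no vote at all are unclassified
    missing <- setdiff(putative_ids, cons$read_id)
    if (length(missing))
      cons <- data.table::rbindlist(list(
        cons, data.table::data.table(read_id = missing, taxid = 0L)))
    env$cons <- cons
    env$tree <- tree
    write_consensus(cons, tree, outputs$consensus)
    tt <- taxa_table(cons, tree)
    env$taxa <- tt
    data.table::fwrite(tt, outputs$taxa, sep = "\t")
  })
  if (is.null(env$cons)) {
    env$tree <- load_taxonomy(config$nodes_dmp, config$names_dmp)
    cons <- data.table::fread(outputs$consensus)
    env$cons <- cons[, .(read_id = as.character(read_id),
                         taxid = as.integer(taxid))]
    env$taxa <- taxa_table(env$cons, env$tree)
  }

  run_stage("reports", unlist(outputs[c("expression", "rollup", "cytoscape",
                                        "heatmap", "summary_tsv", "ledger")]),
            function() {
    # finalise the ledger: annotated vs unidentified
    led <- env$st1$ledger
    ann_ids <- unique(env$gene$map$read_id)
    open <- is.na(led$terminal)
    sel_ann <- open & led$read_id %in% ann_ids
    ledger_record(led, led$read_id[sel_ann], led$mate[sel_ann], "annotated")
    open <- is.na(led$terminal)
    ledger_record(led, led$read_id[open], led$mate[open], "unidentified")
    ledger_write(led, outputs$ledger)

    glen <- data.table::fread(config$gene_lengths, header = FALSE,
                              col.names = c("gene_id", "length_bp"))
    gene_lengths <- stats::setNames(glen$length_bp, glen$gene_id)
    acc <- load_accession_map(config$accession_map)
    gene_taxids <- accession_taxid(unique(env$gene$map$gene_id), acc)
    expr <- expression_table(env$gene$map, gene_lengths, gene_taxids,
                             env$ec$low[, .(target_id, ec)])
    data.table::fwrite(expr, outputs$expression, sep = "\t")

    groups <- rollup_taxa(env$taxa, env$tree, config$taxa_cutoff)
    data.table::fwrite(groups, outputs$rollup, sep = "\t")
    cytoscape_table(expr, groups, outputs$cytoscape)
    long <- ec_rpkm_by_group(expr, groups)
    spm <- data.table::fread(config$ec_superpathways, header = "auto")
    data.table::setnames(spm, 1:2, c("ec", "superpathway"))
    grc <- stats::setNames(groups$read_pairs, groups$label)
    if (nrow(long))
      superpathway_matrix(long, spm, grc, config$heatmap_top_n,
                          outputs$heatmap)
    else data.table::fwrite(data.table::data.table(superpathway = character()),
                            outputs$heatmap)

    summ <- read_summary(led, env$gene$map, env$ec$n_unique_ec,
                         outputs$summary_tsv)
    env$summary <- summ
    quality_histogram(config$fastq_fwd, {
      # "after" = putative mRNA mates from the forward file
      keep <- env$st1$putative
      tmp <- file.path(state_dir, "after.fastq")
      sel <- keep[keep$mate %in% c("fwd", "single")]
      write_fastq(read_table(sel$read_id, sel$mate, sel$sequence,
                             sel$quality), tmp)
      tmp
    }, outputs$quality)

    if (config$keep_interim == "delete")
      unlink(state_dir, recursive = TRUE)
    else if (config$keep_interim == "compress") {
      for (f in list.files(state_dir, full.names = TRUE)) {
        con <- gzfile(paste0(f, ".gz"), "wb")
        writeLines(readLines(f), con)
        close(con)
        unlink(f)
      }
    }
  })
  if (is.null(env$summary)) {
    s <- data.table::fread(outputs$summary_tsv)
    env$summary <- stats::setNames(as.list(s$value), s$field)
  }
  invisible(c(outputs, list(summary = env$summary, out_dir = out_dir)))
}
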