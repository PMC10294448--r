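test_that("rpkm follows the canonical formula and scaling identities", {
  expect_equal(rpkm(10, 500, 1e6), 20)
  expect_equal(rpkm(0, 500, 1e6), 0)
  expect_equal(rpkm(10, 500, 2e6), rpkm(10, 500, 1e6) / 2)
  expect_error(rpkm(1, 0, 100), "gene_length_bp")
  expect_error(rpkm(1, 100, 0), "total_mapped_reads")
})

test_that("the expression table aggregates reads and annotates ECs", {
  map <- data.table::data.table(
    gene_id = c("g1", "g1", "g2"), read_id = c("r1", "r2", "r3"),
    tier = "tier1_nt", n_mates = c(2L, 2L, 1L))
  expr <- expression_table(map, c(g1 = 1000L, g2 = 500L),
                           c(g1 = 70L, g2 = 73L),
                           data.table::data.table(target_id = "g1",
                                                  ec = c("1.1.1.1", "2.2.2.2")))
  expect_equal(expr$read_count[expr$gene_id == "g1"], 4)
  expect_equal(expr$rpkm, rpkm(expr$read_count, expr$length_bp, 5))
  expect_equal(expr$ec_list[expr$gene_id == "g1"], "1.1.1.1,2.2.2.2")
  expect_equal(expr$ec_list[expr$gene_id == "g2"], "")
  expect_error(expression_table(map, c(g1 = 1000L)), "missing gene length")
})

test_that("taxon rollup emits groups by the merge-up rule", {
  tree <- fixture_tree()
  # species 70 at 60% -> own species group
  # species 73 (0.6%) + 74 (0.4%) congeneric under genus 62 -> genus at 1.0%
  # species 72 at 0.2%: no sub-cutoff relatives -> Other
  counts <- data.table::data.table(
    taxid = c(70L, 73L, 74L, 72L, 71L),
    read_pairs = c(600, 6, 4, 2, 388))
  got <- rollup_taxa(counts, tree, 0.01)
  sp70 <- got[got$taxid == 70L]
  expect_equal(sp70$rank, "species")
  expect_equal(sp70$read_fraction, 0.6)
  genus62 <- got[got$taxid == 62L]
  expect_equal(genus62$rank, "genus")
  expect_equal(genus62$read_pairs, 10)
  other <- got[got$label == "Other"]
  expect_equal(other$read_pairs, 2)
  # conservation: group counts sum to input total
  expect_equal(sum(got$read_pairs), sum(counts$read_pairs))
})

test_that("rollup matches the hand-replay oracle on random count vectors", {
  tree <- fixture_tree()
  species <- tree$taxid[unname(tree$rank) == "species"]
  set.seed(30)
  for (i in 1:30) {
    tx <- sample(species, sample(3:6, 1))
    cnt <- sample(1:500, length(tx), replace = TRUE)
    got <- rollup_taxa(data.table::data.table(taxid = tx, read_pairs = cnt),
                       tree, 0.05)
    want <- oracle_rollup(tx, cnt, tree, 0.05)
    expect_equal(sum(got$read_pairs), sum(cnt))
    for (j in seq_len(nrow(got))) {
      k <- if (got$label[j] == "Other") "Other" else as.character(got$taxid[j])
      expect_equal(got$read_pairs[j], want[[k]],
                   info = paste("group", k, "iter", i))
    }
  }
})

test_that("the Cytoscape table conserves per-EC RPKM across taxon groups", {
  tree <- fixture_tree()
  expr <- data.table::data.table(
    gene_id = c("g1", "g2", "g3"),
    length_bp = 1000L, read_count = c(30, 70, 5), rpkm = c(30, 70, 5),
    taxid = c(70L, 73L, 70L),
    ec_list = c("1.1.1.1", "1.1.1.1", ""))
  groups <- rollup_taxa(data.table::data.table(taxid = c(70L, 73L),
                                               read_pairs = c(35, 70)),
                        tree, 0.01)
  tab <- cytoscape_table(expr, groups)
  expect_equal(nrow(tab), 1)   # zero-RPKM / no-EC rows omitted
  expect_equal(tab$total_rpkm, 100)
  group_cols <- setdiff(names(tab), c("ec", "total_rpkm"))
  expect_equal(sum(unlist(tab[, group_cols, with = FALSE])), tab$total_rpkm,
               tolerance = 1e-6)
  expect_equal(unname(unlist(tab[, group_cols, with = FALSE])[
    match("n70", group_cols)]), 30)
})

test_that("the superpathway matrix keeps top-n taxa plus Other", {
  long <- data.table::data.table(
    ec = rep("1.1.1.1", 25),
    label = sprintf("tax%02d", 1:25),
    rpkm = 25:1)
  spm <- data.table::data.table(ec = "1.1.1.1", superpathway = "Glycolysis")
  counts <- stats::setNames(25:1, sprintf("tax%02d", 1:25))
  mat <- superpathway_matrix(long, spm, counts, top_n = 20)
  expect_equal(ncol(mat), 21)  # 20 + Other
  expect_equal(colnames(mat)[21], "Other")
  expect_equal(sum(mat), sum(long$rpkm))
  # single EC / single taxon: 1x1 equal to its RPKM
  one <- superpathway_matrix(
    data.table::data.table(ec = "1.1.1.1", label = "A", rpkm = 7),
    spm, c(A = 10), top_n = 20)
  expect_equal(dim(one), c(1L, 1L))
  expect_equal(one[1, 1], 7)
  # EC in two superpathways counted in both rows
  two <- superpathway_matrix(
    data.table::data.table(ec = "1.1.1.1", label = "A", rpkm = 7),
    data.table::data.table(ec = "1.1.1.1",
                           superpathway = c("P1", "P2")),
    c(A = 10), top_n = 20)
  expect_equal(unname(two[, "A"]), c(7, 7))
  # unmapped EC lands in the Unmapped row
  un <- superpathway_matrix(
    data.table::data.table(ec = "9.9.9.9", label = "A", rpkm = 3),
    spm, c(A = 1), top_n = 20)
  expect_true("Unmapped" %in% rownames(un))
})

test_that("the read summary recomputes its percentages exactly", {
  reads <- make_read_set(10)
  led <- ledger_init(reads)
  k <- function(i) sprintf("r%04d", i)
  ledger_record(led, rep(k(1), 2), c("fwd", "rev"), "low_quality")
  ledger_record(led, rep(k(2), 2), c("fwd", "rev"), "host")
  ledger_record(led, rep(k(3), 2), c("fwd", "rev"), "vector")
  ledger_record(led, rep(k(4:5), each = 2), rep(c("fwd", "rev"), 2),
                "rRNA_tRNA")
  for (i in 6:9) {
    ledger_record(led, rep(k(i), 2), c("fwd", "rev"), "putative_mRNA")
    ledger_record(led, rep(k(i), 2), c("fwd", "rev"), "annotated")
  }
  ledger_record(led, rep(k(10), 2), c("fwd", "rev"), "putative_mRNA")
  ledger_record(led, rep(k(10), 2), c("fwd", "rev"), "unidentified")
  map <- data.table::data.table(gene_id = c("gA", "gA", "gB", "gC"),
                                read_id = k(6:9), tier = "tier1_nt",
                                n_mates = 2L)
  s <- read_summary(led, map, c(low = 5L, high = 3L))
  expect_equal(s$total_reads, 20)
  expect_equal(s$high_quality_reads, 18)
  expect_equal(s$high_quality_pct, 100 * 18 / 20)
  expect_equal(s$host_pct, 100 * s$host_reads / s$total_reads)
  expect_equal(s$rRNA_tRNA_reads, 4)
  expect_equal(s$putative_mRNA_reads, 10)
  # annotated% uses putative mRNA as its denominator
  expect_equal(s$annotated_pct, 100 * s$annotated_reads / s$putative_mRNA_reads)
  expect_equal(s$annotated_reads, 8)
  expect_equal(s$unique_genes, 3)
  expect_equal(s$unique_ec_low, 5L)
  # empty ledger: all zero, percentages defined as 0
  s0 <- read_summary(ledger_init(reads[0]), map[0], c(low = 0, high = 0))
  expect_equal(s0$total_reads, 0)
  expect_equal(s0$high_quality_pct, 0)
  expect_equal(s0$annotated_pct, 0)
})

test_that("N50/L50 follow the cumulative-half definition", {
  got <- n50_l50(c(100, 200, 300))
  expect_equal(got$N50, 300)
  expect_equal(got$L50, 1)   # 300 >= 600/2
  expect_equal(n50_l50(1234), list(N50 = 1234, L50 = 1L))
  eq <- n50_l50(rep(77L, 9))
  expect_equal(eq$N50, 77L)
  expect_error(n50_l50(integer(0)), "empty")
})

test_that("quality histograms bin per-read mean phred and count all reads", {
  uni <- read_table(sprintf("u%d", 1:5), "single", rep("ACGT", 5),
                    rep("IIII", 5))          # mean phred 40
  mix <- read_table(sprintf("m%d", 1:4), "single", rep("ACGT", 4),
                    c("IIII", "!!!!", "5555", "IIII"))
  p1 <- tempfile(fileext = ".fastq"); p2 <- tempfile(fileext = ".fastq")
  suppressWarnings(write_fastq(uni, p1))
  suppressWarnings(write_fastq(mix, p2))
  h <- quality_histogram(p1, p2)
  expect_equal(sum(h$before), 5)
  expect_equal(sum(h$after), 4)
  expect_equal(h$before[h$bin == 40], 5)     # single occupied bin
  expect_equal(h$after[h$bin == 0], 1)
  expect_equal(h$after[h$bin == 20], 1)      # "5" = phred 20
})
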