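test_that("the taxonomy generator builds balanced trees with the seven ranks", {
  one <- make_taxonomy(1, 1)
  # single lineage: root + superkingdom..species = depth 7 below root
  deepest <- one$species
  expect_equal(length(deepest), 1)
  expect_equal(length(lineage(one$tree, deepest)) - 1, 7)
  two <- make_taxonomy(2, 2)
  expect_equal(length(two$species), 2^6)
  ranks <- unique(unname(two$tree$rank))
  expect_setequal(ranks, c("no_rank", "species", "genus", "family", "order",
                           "class", "phylum", "superkingdom"))
})

test_that("generators are byte-deterministic under a fixed seed", {
  d1 <- tempfile(); d2 <- tempfile()
  t1 <- make_taxonomy(2, 2, dir = d1, seed = 5)
  t2 <- make_taxonomy(2, 2, dir = d2, seed = 5)
  expect_equal(readLines(t1$nodes_path), readLines(t2$nodes_path))
  tax <- make_taxonomy(2, 3, seed = 1)
  set.seed(99); sp <- sample(tax$species, 3)
  spec <- community_spec(sp, n_read_pairs = 200, seed = 11)
  r1 <- suppressWarnings(make_reads(spec, dir = tempfile()))
  r2 <- suppressWarnings(make_reads(spec, dir = tempfile()))
  expect_identical(readLines(r1$fastq_fwd), readLines(r2$fastq_fwd))
  expect_identical(readLines(r1$fastq_rev), readLines(r2$fastq_rev))
  expect_identical(r1$truth, r2$truth)
  a1 <- make_alignment_reports(r1, spec)
  a2 <- make_alignment_reports(r2, spec)
  expect_identical(readLines(a1$tier1_sam), readLines(a2$tier1_sam))
  expect_identical(readLines(a1$tier2_m8), readLines(a2$tier2_m8))
})

test_that("planted category fractions are honoured within sampling error", {
  tax <- make_taxonomy(2, 3, seed = 1)
  set.seed(1); sp <- sample(tax$species, 4)
  spec <- community_spec(sp, n_read_pairs = 10000, rrna_fraction = 0.5,
                         host_fraction = 0.0, seed = 3)
  r <- suppressWarnings(make_reads(spec, dir = tempfile()))
  tab <- table(r$truth$category)
  expect_equal(unname(tab[["rRNA_tRNA"]]) >= 4800 &&
                 unname(tab[["rRNA_tRNA"]]) <= 5200, TRUE)  # +-4 sigma
  expect_false("host" %in% names(tab))  # zero fraction -> no host reads
})

test_that("zero-noise alignment reports let the cascade recover truth exactly", {
  tax <- make_taxonomy(2, 3, seed = 1)
  set.seed(2); sp <- sample(tax$species, 3)
  spec <- community_spec(sp, n_read_pairs = 500, seed = 7)
  r <- suppressWarnings(make_reads(spec, dir = tempfile()))
  a <- make_alignment_reports(r, spec, miss_rate = 0, spurious_rate = 0)
  mrna <- r$truth[r$truth$category == "mRNA"]
  reads <- data.table::data.table(
    read_id = rep(mrna$read_id, each = 2), mate = c("fwd", "rev"),
    length = spec$read_length)
  res <- cascade_annotate(reads, a$tier1_sam, a$tier2_m8, a$tier3_m8)
  expect_equal(length(res$unannotated), 0)
  m <- merge(res$map, mrna, by = "read_id")
  expect_true(all(m$gene_id.x == m$gene_id.y))
})

test_that("spurious sub-threshold hits are never assigned", {
  tax <- make_taxonomy(2, 3, seed = 1)
  set.seed(2); sp <- sample(tax$species, 3)
  spec <- community_spec(sp, n_read_pairs = 300, seed = 7)
  r <- suppressWarnings(make_reads(spec, dir = tempfile()))
  a <- make_alignment_reports(r, spec, miss_rate = 1 - 1e-9,
                              spurious_rate = 0.5, seed = 77)
  mrna <- r$truth[r$truth$category == "mRNA"]
  reads <- data.table::data.table(
    read_id = rep(mrna$read_id, each = 2), mate = c("fwd", "rev"),
    length = spec$read_length)
  res <- cascade_annotate(reads, a$tier1_sam, a$tier2_m8, a$tier3_m8)
  expect_equal(nrow(res$map), 0)  # decoys all fall below thresholds
})

test_that("the miss rate depresses the annotated fraction binomially", {
  tax <- make_taxonomy(2, 3, seed = 1)
  set.seed(2); sp <- sample(tax$species, 5)
  spec <- community_spec(sp, n_read_pairs = 4000, seed = 5)
  r <- suppressWarnings(make_reads(spec, dir = tempfile()))
  a <- make_alignment_reports(r, spec, miss_rate = 0.1)
  mrna <- r$truth[r$truth$category == "mRNA"]
  reads <- data.table::data.table(
    read_id = rep(mrna$read_id, each = 2), mate = c("fwd", "rev"),
    length = spec$read_length)
  res <- cascade_annotate(reads, a$tier1_sam, a$tier2_m8, a$tier3_m8)
  frac <- nrow(res$map) / nrow(mrna)
  n <- nrow(mrna)
  sigma <- sqrt(0.9 * 0.1 / n)
  expect_gt(frac, 0.9 - 4 * sigma)
  expect_lt(frac, 0.9 + 4 * sigma)
})

test_that("classifier votes have the stated accuracy and sibling confusions", {
  tax <- make_taxonomy(2, 3, seed = 1)
  set.seed(2); sp <- sample(tax$species, 3)
  spec <- community_spec(sp, n_read_pairs = 800, seed = 9)
  r <- suppressWarnings(make_reads(spec, dir = tempfile()))
  votes <- make_classifier_votes(r, tax$tree,
                                 accuracy = c(gene_lookup = 1, kaiju = 0,
                                              centrifuge = 0.5))
  mrna <- r$truth[r$truth$category == "mRNA"]
  gl <- read_classifier_votes(votes$gene_lookup, "gene_lookup")
  m <- merge(gl, mrna, by = "read_id")
  expect_true(all(m$taxid.x == m$taxid.y))
  kj <- merge(read_classifier_votes(votes$kaiju, "kaiju"), mrna, by = "read_id")
  expect_true(all(kj$taxid.x != kj$taxid.y))
  # wrong votes are congeneric siblings
  sib_ok <- vapply(seq_len(nrow(kj)), function(i) {
    g1 <- lineage(tax$tree, kj$taxid.x[i])
    g2 <- lineage(tax$tree, kj$taxid.y[i])
    g1[length(g1) - 1] == g2[length(g2) - 1]
  }, logical(1))
  expect_true(all(sib_ok))
  cf <- merge(read_classifier_votes(votes$centrifuge, "centrifuge"), mrna,
              by = "read_id")
  acc <- mean(cf$taxid.x == cf$taxid.y)
  sigma <- sqrt(0.25 / nrow(cf))
  expect_gt(acc, 0.5 - 4 * sigma); expect_lt(acc, 0.5 + 4 * sigma)
})

test_that("EC fixtures exercise both stringency modes and stay subset-ordered", {
  tax <- make_taxonomy(2, 3, seed = 1)
  set.seed(2); sp <- sample(tax$species, 3)
  spec <- community_spec(sp, n_read_pairs = 100, seed = 13)
  r <- suppressWarnings(make_reads(spec, dir = tempfile()))
  # fixed draws on the favourable side of every cutoff -> full recovery
  fx <- make_ec_fixture(r, priam_prob_range = c(0.9, 0.9),
                        diamond_log10e_range = c(-20, -20))
  detect <- read_ec_predictions(fx$detect_path)
  priam <- read_ec_predictions(fx$priam_path)
  db <- load_ec_pair_db(fx$pair_db_path)
  rep <- ec_reports(detect, priam, fx$diamond_ec, db)
  truth_ecs <- unique(unlist(r$genes$ecs))
  expect_setequal(rep$high$ec, truth_ecs)
  # detect-only world: diamond silent, merge keeps only DETECT
  fx0 <- make_ec_fixture(r, diamond_sens = 0, seed = 99)
  rep0 <- ec_reports(read_ec_predictions(fx0$detect_path),
                     read_ec_predictions(fx0$priam_path),
                     fx0$diamond_ec, db)
  expect_true(all(rep0$low$sources == "DETECT"))
  # mixed draws: high subset of low per target
  fx1 <- make_ec_fixture(r, seed = 123)
  rep1 <- ec_reports(read_ec_predictions(fx1$detect_path),
                     read_ec_predictions(fx1$priam_path),
                     fx1$diamond_ec, load_ec_pair_db(fx1$pair_db_path))
  key <- function(x) paste(x$target_id, x$ec)
  expect_true(all(key(rep1$high) %in% key(rep1$low)))
})
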