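test_that("cigar coverage counts aligned operations only", {
  expect_equal(cigar_coverage("100M", 100), 1.0)
  expect_equal(cigar_coverage("50M50S", 100), 0.5)
  expect_equal(cigar_coverage("40M10I40M", 100), 0.8)  # insertions excluded
  expect_equal(cigar_coverage("30=10X10D50S", 100), 0.4)
  expect_error(cigar_coverage("10Q", 100), "malformed")
  expect_error(cigar_coverage("M10", 100), "malformed")
})

test_that("cigar coverage equals an independent tokenizer on random CIGARs", {
  set.seed(9)
  for (i in 1:200) {
    cg <- random_cigar()
    rl <- sample(50:200, 1)
    expect_equal(cigar_coverage(cg, rl), oracle_cigar_coverage(cg, rl))
  }
})

test_that("cigar coverage agrees with GenomicAlignments op accounting", {
  skip_if_not_installed("GenomicAlignments")
  set.seed(10)
  cigars <- replicate(50, random_cigar())
  tab <- GenomicAlignments::cigarOpTable(cigars)
  aligned <- rowSums(tab[, c("M", "=", "X"), drop = FALSE])
  expect_equal(cigar_coverage(cigars, 100), pmin(aligned / 100, 1))
})

test_that("SAM hits are accepted at exactly the 90% coverage threshold", {
  aln <- data.table::data.table(mapped = TRUE, cigar = c("90M10S", "89M11S"))
  got <- accept_sam_hit(aln, 100)
  expect_true(got[1])    # 0.90 exactly passes ("falls below" rejects)
  expect_false(got[2])   # 0.89 rejected
  expect_error(accept_sam_hit(data.table::data.table(mapped = FALSE,
                                                     cigar = "10M"), 100),
               "mapped")
})

test_that("tabular hits pass at thresholds and fail below any clause", {
  thr <- hit_thresholds()
  at <- data.table::data.table(percent_identity = 85, alignment_length = 65,
                               bitscore = 60)
  expect_true(accept_tabular_hit(at, 100))
  low_id <- data.table::copy(at); low_id$percent_identity <- 84.9
  expect_false(accept_tabular_hit(low_id, 100))
  low_len <- data.table::copy(at); low_len$alignment_length <- 64.9
  expect_false(accept_tabular_hit(low_len, 100))
  low_bs <- data.table::copy(at); low_bs$bitscore <- 59.9
  expect_false(accept_tabular_hit(low_bs, 100))
  # translated search: effective length floor(nt/3)
  prot <- data.table::data.table(percent_identity = 90,
                                 alignment_length = 22, bitscore = 80)
  expect_true(accept_tabular_hit(prot, 100, translated = TRUE))  # 22/33 = 67%
  prot$alignment_length <- 21                                    # 21/33 = 64%
  expect_false(accept_tabular_hit(prot, 100, translated = TRUE))
})

test_that("random tabular hits match the three-clause boolean oracle", {
  set.seed(12)
  thr <- hit_thresholds()
  for (i in 1:300) {
    h <- data.table::data.table(
      percent_identity = runif(1, 60, 100),
      alignment_length = sample(10:120, 1),
      bitscore = runif(1, 20, 200))
    qlen <- sample(60:150, 1)
    tr <- sample(c(TRUE, FALSE), 1)
    expect_equal(accept_tabular_hit(h, qlen, tr, thr),
                 oracle_accept_tabular(h$percent_identity, h$alignment_length,
                                       h$bitscore, qlen, tr, thr))
  }
})

test_that("best assignment takes the earliest maximal score", {
  b <- best_assignment(c("g1", "g2", "g3"), c(10, 20, 20))
  expect_equal(b$gene_id, "g2")  # tie -> first of the maxima
  expect_equal(best_assignment("solo", 5)$gene_id, "solo")
  expect_error(best_assignment(character(0), numeric(0)), "empty")
  set.seed(13)
  for (i in 1:300) {
    n <- sample(1:8, 1)
    s <- sample(1:5, n, replace = TRUE)
    g <- sprintf("g%d", seq_len(n))
    expect_equal(best_assignment(g, s)$gene_id, g[oracle_best(s)])
  }
})

test_that("pair resolution assigns both mates to the higher-scoring gene", {
  expect_equal(resolve_pair(list(gene_id = "G", score = 10),
                            list(gene_id = "G", score = 8)), "G")
  expect_equal(resolve_pair(list(gene_id = "G1", score = 70),
                            list(gene_id = "G2", score = 90)), "G2")
  expect_equal(resolve_pair(list(gene_id = "G1", score = 50),
                            list(gene_id = "G2", score = 50)), "G1")  # tie: fwd
  expect_equal(resolve_pair(list(gene_id = "G1", score = 50), NULL), "G1")
  expect_null(resolve_pair(NULL, NULL))
})

sam_line <- function(id, flag, gene, cigar, as, seq = strrep("A", 100)) {
  sprintf("%s\t%d\t%s\t1\t30\t%s\t*\t0\t0\t%s\t%s\tAS:i:%d",
          id, flag, gene, cigar, seq, strrep("I", nchar(seq)), as)
}

test_that("the SAM reader extracts mates, AS tags and falls back to MAPQ", {
  p <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6",
               "@SQ\tSN:g1\tLN:1000",
               sam_line("r1", 99, "g1", "100M", 77),
               sam_line("r1", 147, "g1", "100M", 70),
               "r2\t0\tg1\t1\t42\t100M\t*\t0\t0\tAAAA\tIIII",  # no AS -> MAPQ
               "r3\t4\t*\t0\t0\t*\t*\t0\t0\tAAAA\tIIII"), p)
  sam <- read_sam(p)
  expect_equal(nrow(sam), 4)
  expect_equal(sam$mate[1:2], c("fwd", "rev"))
  expect_equal(sam$alignment_score[1:3], c(77, 70, 42))
  expect_false(sam$mapped[4])
  expect_equal(sam$gene_id[4], "")
})

test_that("the SAM reader agrees with Rsamtools on a BAM round-trip", {
  skip_if_not_installed("Rsamtools")
  p <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               "@SQ\tSN:g1\tLN:1000",
               "@SQ\tSN:g2\tLN:500",
               sam_line("r1", 99, "g1", "100M", 77),
               sam_line("r1", 147, "g2", "60M40S", 31),
               sam_line("r2", 0, "g2", "95M5S", 55)), p)
  bam <- Rsamtools::asBam(p, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  rec <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "rname", "cigar"),
    tag = "AS"))[[1]]
  sam <- read_sam(p)
  expect_equal(sam$read_id, as.character(rec$qname))
  expect_equal(sam$gene_id, as.character(rec$rname))
  expect_equal(sam$cigar, rec$cigar)
  expect_equal(sam$alignment_score, as.numeric(rec$tag$AS))
})

cascade_fixture <- function(dir = tempfile("casc")) {
  dir.create(dir)
  # five reads: r1 tier1; r2 tier1-reject + tier2; r3 tier2; r4 tier3; r5 none
  sam <- c("@SQ\tSN:gA\tLN:1000",
           sam_line("r1", 99, "gA", "100M", 90),
           sam_line("r1", 147, "gA", "100M", 88),
           sam_line("r2", 99, "gA", "50M50S", 10))  # below 90% coverage
  m8_2 <- c("r2\tgB\t95.0\t100\t1\t0\t1\t100\t1\t100\t1e-30\t150.0",
            "r3\tgC\t90.0\t80\t1\t0\t1\t80\t1\t80\t1e-20\t120.0",
            # r1 present again in tier 2: must be ignored (already assigned)
            "r1\tgZ\t99.0\t100\t1\t0\t1\t100\t1\t100\t1e-40\t200.0")
  m8_3 <- c("r4\tpD\t92.0\t30\t1\t0\t1\t30\t1\t30\t1e-15\t95.0",
            "r5\tpE\t50.0\t10\t1\t0\t1\t10\t1\t10\t1.0\t20.0")  # rejected
  writeLines(sam, file.path(dir, "t1.sam"))
  writeLines(m8_2, file.path(dir, "t2.m8"))
  writeLines(m8_3, file.path(dir, "t3.m8"))
  reads <- data.table::rbindlist(lapply(sprintf("r%d", 1:5), function(id)
    data.table::data.table(read_id = id, mate = c("fwd", "rev"), length = 100L)))
  list(dir = dir, reads = reads)
}

test_that("the cascade assigns by tier precedence and conserves reads", {
  fx <- cascade_fixture()
  res <- cascade_annotate(fx$reads, file.path(fx$dir, "t1.sam"),
                          file.path(fx$dir, "t2.m8"), file.path(fx$dir, "t3.m8"))
  m <- res$map
  expect_equal(m$gene_id[m$read_id == "r1"], "gA")      # tier 1 kept over tier 2
  expect_equal(m$tier[m$read_id == "r1"], "tier1_nt")
  expect_equal(m$gene_id[m$read_id == "r2"], "gB")      # fell through to tier 2
  expect_equal(m$gene_id[m$read_id == "r3"], "gC")
  expect_equal(m$gene_id[m$read_id == "r4"], "pD")
  expect_equal(m$tier[m$read_id == "r4"], "tier3_prot")
  expect_equal(res$unannotated, "r5")
  expect_equal(anyDuplicated(m$read_id), 0)             # injectivity
  expect_equal(nrow(m) + length(res$unannotated), 5)    # conservation
  expect_true(all(m$n_mates == 2L))
})

test_that("chunked and unchunked cascades produce identical maps", {
  fx <- cascade_fixture()
  a <- cascade_annotate(fx$reads, file.path(fx$dir, "t1.sam"),
                        file.path(fx$dir, "t2.m8"), file.path(fx$dir, "t3.m8"))
  b <- cascade_annotate(fx$reads, file.path(fx$dir, "t1.sam"),
                        file.path(fx$dir, "t2.m8"), file.path(fx$dir, "t3.m8"),
                        chunk_size = 2)
  expect_equal(a$map, b$map)
  expect_equal(a$unannotated, b$unannotated)
})

test_that("raising thresholds never increases accepted hits", {
  set.seed(14)
  hits <- data.table::data.table(
    percent_identity = runif(200, 60, 100),
    alignment_length = sample(30:120, 200, replace = TRUE),
    bitscore = runif(200, 20, 200))
  base <- sum(accept_tabular_hit(hits, 100, FALSE, hit_thresholds()))
  for (i in 1:20) {
    thr <- hit_thresholds(identity_min = runif(1, 85, 100),
                          aln_len_fraction_min = runif(1, 65, 100),
                          bitscore_min = runif(1, 60, 150))
    expect_lte(sum(accept_tabular_hit(hits, 100, FALSE, thr)), base)
  }
})

test_that("contig gene models resolve multi-gene hits by alignment score", {
  gff <- tempfile(fileext = ".gff")
  writeLines(c("##gff-version 3",
               "contig1\tpred\tgene\t1\t500\t.\t+\t.\tID=cg1",
               "contig1\tpred\tgene\t501\t900\t.\t-\t.\tID=cg2"), gff)
  idx <- read_contig_gene_index(gff)
  expect_equal(idx$gene_id, c("cg1", "cg2"))
  expect_equal(idx$end, c(500L, 900L))
  sam <- tempfile(fileext = ".sam")
  writeLines(c("@SQ\tSN:cg1\tLN:500", "@SQ\tSN:cg2\tLN:400",
               sam_line("r1", 0, "cg1", "100M", 60),
               sam_line("r1", 256, "cg2", "100M", 80),  # secondary, higher AS
               sam_line("r2", 0, "cg1", "100M", 50)), sam)
  crm <- data.table::data.table(contig_id = "contig1",
                                read_id = c("r1", "r2"))
  got <- map_reads_to_contig_genes(crm, idx, sam)
  expect_equal(got$gene_id[got$read_id == "r1"], "cg2")
  expect_equal(got$gene_id[got$read_id == "r2"], "cg1")
  expect_equal(anyDuplicated(got$read_id), 0)
  bad_sam <- tempfile(fileext = ".sam")
  writeLines(c("@SQ\tSN:ghost\tLN:100", sam_line("r9", 0, "ghost", "100M", 9)),
             bad_sam)
  expect_error(map_reads_to_contig_genes(crm, idx, bad_sam), "absent")
})

test_that("reference aligner settings for contig mapping are exposed", {
  expect_equal(bwa_contig_params(), list(B = 40L, O = 60L, E = 10L, L = 50L))
})
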