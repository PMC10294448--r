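# mtxannot

Post-processing toolkit for metatranscriptomic annotation pipelines.

Whole-community RNA sequencing (metatranscriptomics) asks not just *who is
there* but *what they are doing*. Between the heavy external tools — read
trimmers, host/vector/rRNA filters, nucleotide and protein aligners,
short-read taxonomic classifiers, enzyme predictors — sits a layer of
bookkeeping and decision rules that determines what a pipeline actually
reports: which reads count as putative mRNA, which homology hits are
accepted, which gene each read belongs to, which taxon and which enzyme each
gene is credited to, and how all of it is normalised and summarised.
`mtxannot` implements that layer as a testable R library with a thin
command-line wrapper, consuming the tools' standard report formats (FASTQ,
SAM, 12-column BLAST tabular, NCBI taxonomy dumps, classifier and EC
predictor TSVs) and producing the full set of sample reports. A synthetic
generator with complete ground truth stands in for the external tools, so
every rule is verifiable offline.

It is intended for pipeline developers and bioinformaticians who need the
decision rules of a metatranscriptomics workflow to be explicit, inspectable
and reproducible, rather than buried in glue scripts.

## The rules it implements

**Read bookkeeping.** Every read (per mate) travels through a ledger and
ends in exactly one terminal category — low quality, host, vector,
rRNA/tRNA, annotated, or unidentified — so terminal counts always sum to the
raw input. Paired-end rules: a mate orphaned by a per-mate filter is
promoted to singleton; for contaminant filters, `high` stringency assigns
both mates of a pair to the category when either hits, `low` filters only
the hitting mate; exact-sequence duplicates are collapsed before filtering
and repopulated afterwards, inheriting their representative's fate.

**Tiered gene annotation.** A SAM tier followed by two BLAST-tabular tiers
(nucleotide, then translated protein); reads accepted at a tier are excluded
from later tiers. Acceptance: CIGAR coverage (M/=/X over read length) ≥ 0.90
for SAM; percent identity ≥ 85, alignment length ≥ 65% of the effective
query length (`floor(nt/3)` residues for the protein tier), and bitscore
≥ 60 for tabular hits. Multiple hits resolve to the earliest
maximal-score hit; disagreeing pair mates both go to the higher-scoring
gene. The resulting gene-to-read map assigns each read at most once.

**Ensemble enzyme (EC) annotation.** All profile-tool (DETECT-like) calls,
plus ECs agreed by both the PRIAM-like and similarity-search sources —
e-value < 1e-5 for the low-stringency report, e-value < 1e-10 with PRIAM
probability ≥ 0.5 for the high-stringency report. Multi-EC targets are
validated against a curated co-occurrence pair table (top two by score,
then pair check).

**Weighted consensus taxonomy.** Per read, a gene-derived taxid vote (weight
0.6) and two classifier votes (0.2 each) deposit their weights along their
lineages in an NCBI-style taxonomy; the consensus is the deepest node with a
strict weight majority, ties resolving to the LCA.

**Reporting.** The 16-field read summary; gene RPKM tables
(`count × 1e9 / (length_bp × total_mapped)`); taxon rollup merging sub-1%
taxa up the ranks; a Cytoscape-compatible per-EC table stratified by taxon
group; a superpathway × top-20-taxa RPKM matrix; N50/L50; before/after
quality histograms.

## Worked example

Simulate a five-species community (5,000 read pairs, seed 42) and run the
full pipeline:

```r
library(mtxannot)

sim <- simulate_sample("demo", seed = 42, n_species = 5, n_read_pairs = 5000)
cfg <- validate_config(sim$config_path)
res <- run_pipeline(cfg, "demo/out")
str(res$summary)
```

The read summary printed by this run:

```
total_reads            10000
high_quality_reads     9722
high_quality_pct       97.22
host_reads             512
host_pct               5.12
vector_reads           196
vector_pct             1.96
rRNA_tRNA_reads        3438
rRNA_tRNA_pct          34.38
putative_mRNA_reads    5576
putative_mRNA_pct      55.76
annotated_reads        5576
annotated_pct          100
unique_genes           50
unique_ec_high         34
unique_ec_low          34
```

Reading it: of 10,000 input reads (5,000 pairs), 2.78% were planted as low
quality, 5.12% as host, 1.96% as vector and 34.38% as rRNA/tRNA — all within
sampling error of the generator's planted fractions (3%, 5%, 2%, 35%) — and
the remaining 55.76% are putative mRNA. With zero alignment noise the
cascade annotates 100% of them to the community's 50 genes. The taxa table
for the same run recovers the planted read-pair counts exactly:

```
   taxid     taxon read_pairs
1:   659 Spe_221_1       1423
2:   473 Spe_159_1        732
3:   519 Spe_174_2        362
4:   589 Spe_197_3        173
5:   687 Spe_230_2         98
```

and `demo/out/` also contains the read ledger, gene-to-read map, low/high
EC reports, per-read consensus with lineages, taxon rollup, gene RPKM table
(`gene_expression.tsv`), Cytoscape EC table and the superpathway matrix
(`EC_coverage.csv`).

The same thing from a shell, via the bundled CLI:

```sh
cli=$(Rscript -e 'cat(system.file("cli", "mtxannot", package = "mtxannot"))')
Rscript "$cli" simulate --output demo --seed 42 --n-pairs 5000
Rscript "$cli" run --config demo/config.ini --output demo/out
Rscript "$cli" report --output demo/out
```

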