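---
title: "Methods: read bookkeeping, tiered annotation and consensus taxonomy in mtxannot"
author: "mtxannot developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: read bookkeeping, tiered annotation and consensus taxonomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtxannot)
```

## Scope and model

`mtxannot` implements the bespoke computational layer of a
metatranscriptomics annotation pipeline: the bookkeeping and decision rules
that sit *between* the heavy external tools (read trimmers, aligners,
short-read classifiers, enzyme predictors), consuming their standard report
formats and producing annotated, taxon-stratified expression tables. The
external tools themselves are out of scope: their outputs are inputs here,
and a ground-truthed synthetic generator stands in for them so that every
rule is testable offline.

The pipeline view of a sample is a set of reads, each of which must end in
exactly one terminal category:

* `low_quality` — failed quality trimming;
* `host`, `vector`, `rRNA_tRNA` — matched a contaminant filter;
* `annotated` — survived all filters (putative mRNA) and was assigned to a
  gene or protein;
* `unidentified` — putative mRNA that no annotation tier accepted.

This exhaustive-and-exclusive property ("read conservation") is enforced by
the `ReadLedger`: every filter step appends to a per-read trajectory, and the
terminal category counts must sum to the raw input count. The read summary
table's percentages are recomputed from these counters, so they are
consistent by construction.

## Paired-read rules

Paired-end data introduce three rules that the ledger implements exactly:

* **Orphan promotion.** When a per-mate filter (quality) removes one mate of
  a pair, the survivor is moved to the singletons collection and continues
  alone.
* **Pair-filter stringency.** For the host, vector and rRNA/tRNA filters, the
  default (`high`) stringency assigns *both* mates to the filter category
  when either mate hits; the permissive (`low`) stringency filters only the
  hitting mate and promotes the survivor to singleton.
* **Duplicate repopulation.** Exact-sequence duplicates are collapsed before
  the expensive filters and re-expanded afterwards; every duplicate inherits
  the fate of its cluster representative, so filtered categories are
  reported *including duplicates*. Duplicate detection is exact full-length
  identity: the upstream clustering this emulates runs at 100% identity, and
  only the collapse/repopulate accounting is load-bearing downstream.

## Tiered gene annotation

Putative mRNA reads are annotated by a cascade of three homology tiers:
a nucleotide aligner reporting SAM, a second nucleotide tier and a
translated-protein tier both reporting 12-column BLAST tabular (m8). Reads
accepted at a tier are excluded from later tiers, and a read id may appear in
at most one gene's read list (asserted after every tier).

Acceptance rules, with their package defaults:

| rule | default | applies to |
|---|---|---|
| CIGAR coverage ≥ | 0.90 | SAM tier |
| percent identity ≥ | 85 | m8 tiers |
| alignment length / effective query length ≥ | 65% | m8 tiers |
| bitscore ≥ | 60 | m8 tiers |

All thresholds use "reject if it falls below" semantics, so values exactly
at a threshold pass. CIGAR coverage counts M/`=`/X operations only:
insertions, deletions and clips are not reference-aligned bases. Coverage is
measured against the full read length including soft-clips (the alternative,
the aligned query span, would make the rule tautological for clipped reads).
For the translated tier the effective query length is `floor(nt/3)` residues,
matching the units of the m8 alignment-length column for protein searches.

Multiple hits for one read are adjudicated by score — the AS tag for SAM
(falling back to MAPQ when absent), the bitscore for m8 — with a strict
"must exceed the previous best" scan, so ties resolve to the earliest hit in
report order. Both mates of a pair are assumed to derive from one transcript:
when their best hits disagree, both reads are assigned to the gene with the
higher score (the forward mate's gene on a tie). Reads assembled into contigs
are mapped to the discrete gene models predicted on each contig by the same
SAM rule; the recommended aligner settings for that step (mismatch penalty
40, gap open 60, gap extension 10, clipping penalty 50) are recorded in
`bwa_contig_params()` for users running the external aligner, but only the
resulting SAM is consumed.

Annotation is chunkable: because every decision is per read id, processing
the read set in chunks (50,000 reads by default) and concatenating the
per-chunk results is exactly equivalent to one pass, and the test suite
asserts byte-identical outputs for chunked and unchunked runs.

## Ensemble enzyme annotation

Three EC prediction sources are combined per gene/protein:

* all calls from the profile-based predictor (DETECT-like) are always kept;
* calls agreed on by both the PRIAM-like predictor and the similarity search
  (DIAMOND-like) are added subject to a stringency policy: e-value < 1e-5
  for the low-stringency report; e-value < 1e-10 *and* PRIAM probability
  ≥ 0.5 for the high-stringency report.

Multi-EC targets are validated against a curated table of EC pairs observed
to co-occur on one protein. When more than two ECs are predicted, the two
highest-scoring are kept first (score ties broken by lexicographic EC order),
then the surviving pair is checked against the table; an unsupported pair is
reduced to its higher-scoring member rather than deleted outright, since
symmetric deletion could discard profile-tool calls that the ensemble always
retains. The order — reduce to two, then validate — is a package decision;
the alternative order (validate all pairs first) is equivalent for ≤ 2 ECs
and differs only for rare 3+-EC targets. The unified score per EC is the
DETECT probability when present, else the PRIAM probability, else
`1 − min(evalue, 1)` so that similarity-only calls remain rankable.

The high-stringency report is required to be a subset of the low-stringency
report per target after identical co-occurrence filtering; a violation is an
invariant error rather than a silent repair.

## Weighted consensus taxonomy

Each read receives up to three votes: a gene-derived vote (the taxid of the
assigned gene's accession, looked up in an accession-to-taxid map), and one
vote each from two short-read classifiers. Votes are merged by a
WEVOTE-style weighted-lineage majority: each classified vote deposits its
weight (0.6 for the gene lookup, 0.2 for each classifier) on every node of
its lineage; with `W` the total weight of classified votes, the consensus is
the deepest node whose accumulated weight strictly exceeds `W/2`, with
equal-depth ties resolved to the lowest common ancestor of the tied nodes.
Unclassified votes (taxid 0) are excluded from `W` rather than voting for the
root, so classifiers fill gaps in the gene-derived annotation without
diluting it. The published consensus tool's internal scoring is not restated
by its authors at this level of detail; the rule above reproduces its
documented behaviour (weights, tree-based consensus, gap covering) and is
independently testable against a brute-force accumulator, which the test
suite does on randomized vote sets. Contig-derived reads vote once per read
using the contig gene's taxid; voting once per contig would weight long
contigs less than their read support and is noted as the alternative.

## Reporting

* **RPKM** is the canonical `count × 1e9 / (length_bp × total_mapped)`; for
  translated-tier hits the gene length is 3× the protein length so the
  normalisation stays on the nucleotide scale. Multi-mapped reads are never
  fractionally split — each read counts once, for its single assigned gene.
* **Taxon rollup** starts at species: any taxon holding at least the cutoff
  fraction (default 1%) of reads is emitted at its own (deepest named) rank;
  sub-cutoff taxa are merged with sub-cutoff relatives sharing their genus,
  then family, order, class and phylum, each group being emitted at the
  first rank where it reaches the cutoff; whatever remains below cutoff at
  phylum is pooled into `Other`. Group counts are conserved exactly.
* **The Cytoscape table** lists one row per expressed EC with its total RPKM
  and one column per taxon group; the group columns sum to the total within
  1e-6 (floating-point only).
* **The superpathway matrix** sums each taxon group's EC RPKM within each
  superpathway, keeps the 20 most read-abundant groups and pools the rest
  into `Other`; ECs missing from the superpathway map fall into an
  `Unmapped` row so nothing is dropped silently.
* **N50/L50** use the cumulative-half definition on descending contig
  lengths. **Quality histograms** bin per-read mean phred into integer bins
  0–41; the bin width is not externally specified and integer bins are the
  package's choice.

## The synthetic generator

`simulate_sample()` plants a community with full ground truth: a balanced
taxonomy with all seven named ranks, species with gene repertoires and
geometric relative abundances, per-read true categories, and the
corresponding aligner/classifier/EC-predictor outputs. Default conditions
were chosen once as realistic mid-range values for an Illumina
metatranscriptome and are not tuned per test: 100 bp paired reads, 10 genes
of 600–1200 bp per species, contaminant fractions of 5% host, 2% vector,
35% rRNA/tRNA, 3% low-quality, and a 0.5% substitution rate on mRNA-derived
reads. The acceptance checks run on a five-species community of 10,000 read
pairs.

Noise is injected orthogonally: `miss_rate` removes a read's correct hit,
`spurious_rate` adds decoy hits constructed to fail the acceptance
thresholds, and classifier errors vote a *congeneric sibling* species — the
confusion mode actually observed between closely related genomes — so that
consensus behaviour is observable. With zero noise the construction
guarantees exact recovery; with stated noise, recovery is checked against
4σ binomial bounds.

What the generator does **not** emulate: realistic quality-by-cycle error
profiles, indels, chimeric reads, strain-level reference mismatch, or
assembly. Passing tests therefore demonstrate the correctness of the
decision rules and bookkeeping on well-formed inputs, not the end-to-end
accuracy of any external aligner or classifier on real data.

## Numerical and degenerate-input choices

* Thresholds compare with ≥ (at-threshold passes), matching the documented
  "falls below … rejected" semantics.
* Empty inputs produce empty (not absent) outputs; percentages over empty
  denominators are defined as 0 in the read summary.
* Taxid 0 is reserved for "unclassified" and is never a tree member;
  classifier rows flagged unclassified vote 0.
* When both host and another filter would claim a read, filters run in the
  fixed order host → vector → rRNA/tRNA and the first claim wins; the
  upstream ordering is not externally specified, and this order is recorded
  as the package's convention.
* Merged taxids (taxonomy dump revisions) are not handled; fixture
  taxonomies avoid them.

## Orchestration

`run_pipeline()` executes ledger → gene annotation → enzyme annotation →
consensus → reports, writing a JSON checkpoint per stage; a rerun skips
stages whose checkpoints and outputs are intact and re-executes from the
first broken stage. Resume granularity is the stage, not the within-stage
shard: shard bookkeeping is infrastructure rather than method. Interim files
can be kept, gzip-compressed or deleted per configuration. The CLI
(`inst/cli/mtxannot`) exposes `run`, `simulate` and `report` subcommands and
handles one sample per invocation.

Problem sizes in the shipped tests (a few hundred to 10,000 read pairs,
4–6 species, toy taxonomies of tens to hundreds of nodes) were chosen so the
whole suite exercises every rule, including the 10,000-pair acceptance
conditions, while remaining quick to run on a laptop.
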