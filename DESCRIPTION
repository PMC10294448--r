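Package: mtxannot
Title: Metatranscriptome Read Annotation, Consensus Taxonomy and Reporting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for metatranscriptomic annotation
    pipelines. Tracks every sequencing read through quality, host, vector and
    rRNA/tRNA filtering with orphan-promotion and duplicate-repopulation
    bookkeeping; post-processes tiered homology reports (SAM, then two
    BLAST-tabular tiers) into a gene-to-read map under configurable acceptance
    thresholds; combines three enzyme-commission prediction sources into low-
    and high-stringency reports with co-occurrence validation; assigns per-read
    taxonomy by weighted lineage consensus over a gene-derived vote and two
    short-read classifiers; and produces read-summary, RPKM, taxon-rollup,
    Cytoscape and superpathway outputs. A synthetic fixture generator with
    known ground truth stands in for the aligners, classifiers and reference
    databases so that every stage is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    BiocGenerics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    GenomicAlignments,
    Rsamtools,
    optparse
Config/testthat/edition: 3
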