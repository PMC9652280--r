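Package: strainscan
Title: Reference-Free Strain Comparison by Canonical k-mer Content
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reference-free comparison of two sequenced animal strains
    against an annotated reference genome using canonical k-mer content.
    Reads are decomposed into canonical k-mers, per-individual occurrence
    thresholds are inferred from the k-mer histogram, individual k-mer sets
    are aggregated into strain-level membership, and the reference is
    scanned to call altered base pairs, variants (maximal altered runs) and
    insertion signatures, which are then aggregated per gene over gene
    spans, coding spans and exon unions. Includes an in-silico PCR and
    restriction-digest (RFLP) genotyper and a fully deterministic synthetic
    cohort generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'kmer-engine.R'
    'strain-compare.R'
    'annotation.R'
    'genotyping.R'
    'synthetic-data.R'
    'pipeline.R'
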