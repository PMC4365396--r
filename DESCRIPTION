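Package: exocomp
Title: Combined Hybrid-Capture Exome and Complement Amplicon Panel Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale reimplementation of a combined targeted-enrichment
    workflow for Mendelian variant discovery: coverage accounting for
    hybrid-capture whole-exome sequencing (WES), design and in-silico
    validation of a complementary selective-circularization amplicon panel
    (CCCS) over CDS bases that WES under-covers, read-pair rescue by
    unique-minimum-mismatch realignment, threshold-based SNV/indel calling
    with zygosity classification, WES/CCCS call-set merging, and
    inheritance-aware candidate filtering on pedigrees. Includes a
    synthetic-data generator (reference, gene models, diploid pedigree
    genomes with planted variants, capture-biased and amplicon reads) so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    data.table
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    Rsamtools,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
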