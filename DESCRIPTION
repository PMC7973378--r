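Package: promoscan
Title: Promoter Hexamer Motif Enrichment for Trend-Clustered Gene Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies transcription-factor recognition motifs
    over-represented in the promoters of co-regulated gene sets. Starting
    from a genome (FASTA), gene models (GFF3) and an FPKM expression matrix
    from a two-genotype by two-treatment design, the pipeline selects trend
    clusters by hierarchical clustering, extracts fixed-length upstream
    promoter windows, counts hexamer (k-mer) motifs in foreground versus
    genome-wide promoters, scores each motif with an enrichment fraction and
    a hypergeometric test with Benjamini-Hochberg false discovery rate
    control, and annotates retained motifs against a bundled table of known
    plant cis-regulatory elements. A seeded synthetic-data generator
    produces toy genomes, planted promoter motifs and planted expression
    trends so that every stage is testable without external downloads.
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
    Biostrings,
    rtracklayer,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: MotifDiscovery, SequenceMatching, GeneExpression, Clustering
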