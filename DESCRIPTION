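Package: lncfeather
Title: Identification, Classification and Characterization of Long
    Non-Coding RNAs from Assembled Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for discovering long non-coding RNAs
    (lncRNAs) from strand-specific RNA-seq transcript assemblies. Filters
    assembled isotigs by strand, annotation overlap, length and
    expression; calls putative lncRNAs as the consensus of three coding
    potential filters (CPC-style score, PLEK-style score, protein domain
    E-value); classifies them positionally into intergenic (lincRNA),
    intronic and antisense (lncNAT) classes; computes genomic and
    expression features including mean conservation, transposable element
    overlap and Jensen-Shannon tissue specificity; clusters expression
    profiles by WPGMA; calls differential expression with an empirical
    noise-distribution probability; and selects candidate lncRNAs by
    cluster membership, regional differential expression and cross
    species sequence similarity. Ships a deterministic synthetic data
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    igraph,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
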