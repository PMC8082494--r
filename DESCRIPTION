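Package: ligandomics
Title: Integrated Immunopeptidome and Proteome Differential Presentation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for interpreting MHC-presented peptide
    (pMHC) repertoires against the underlying proteome. Covers construction of
    variant protein sequences and target-decoy search databases, TMT
    reporter-channel differential protein expression, replicate-consistency and
    exclusive-repertoire analysis of MHC class I and class II ligandomes,
    consolidation of overlapping peptides into core epitopes with minimum-value
    imputation and differential presentation tests, allele-specific
    position-weight-matrix binding scores with percentile ranks and a
    Gibbs-sampling motif clusterer scored by Kullback-Leibler divergence,
    rank-based classification of peptides into expression-driven versus
    processing-driven categories, and absolute quantification of variant
    peptides against spiked heavy-isotope standards. A synthetic-data generator
    emulates all inputs with ground-truth labels so every stage is testable
    without raw mass-spectrometry data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
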