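Package: codonBias
Title: Codon Usage Bias Indices, Optimal Codon Detection and
    Cross-Genome Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for synonymous codon usage bias analysis of coding
    sequence collections: codon counting from CDS FASTA, base-composition
    indices (A3s/T3s/G3s/C3s, GC3s, GC, positional GC), relative synonymous
    codon usage (RSCU), Wright's effective number of codons (ENC) with the
    expected-ENC curve, PR2-bias coordinates, the P2 translational-selection
    index, optimal-codon determination from ENC-extreme gene sets, one-way
    ANOVA with Duncan's multiple range test, index correlations, RSCU-based
    hierarchical clustering, and a mutation-selection coding-sequence
    simulator providing ground truth for the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils-codons.R'
    'genetic-code.R'
    'codon-counts.R'
    'composition.R'
    'indices.R'
    'selection.R'
    'compare.R'
    'simulate.R'
    'pipeline.R'
    'seqio.R'
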