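Package: somaticAAS
Title: Harmful Somatic Amino Acid Substitutions and Affected Pathways in
    Cancer Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Annotates somatic single-nucleotide variants onto the longest
    protein-coding transcript per gene, filters amino acid substitutions
    (AASs) by externally predicted harmfulness, and characterises the
    resulting mutational landscape: trinucleotide substitution spectra,
    amino acid substitution matrices, length-normalised domain mutation
    densities, recurrence-based prioritisation of driver proteins,
    hypergeometric GO and pathway enrichment with Benjamini-Hochberg FDR,
    functional-interaction-network average-degree statistics, and
    cross-cancer pathway overlap networks. Ships a synthetic cohort
    generator with planted drivers, spectrum biases, enriched pathways and
    correlated harmfulness probabilities so that every stage has a
    recovery-based test without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    igraph,
    jsonlite,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, SomaticMutation, VariantAnnotation, Pathways,
    Network, GeneSetEnrichment
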