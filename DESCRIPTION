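Package: viromeflow
Title: Faecal Virome Curation and Longitudinal Diversity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for shotgun faecal virome studies with
    repeated sampling designs. Curates assembled contigs into a nonredundant
    viral database using pooled evidence (reference hits, circular topology,
    viral-protein enrichment tiers, dark-matter rescue) with contaminant
    removal, annotates open reading frames, phage lysogeny and putative
    family, groups viruses into pseudogenus-level clusters by shared protein
    content, quantifies per-sample abundance under a tiered
    breadth-of-coverage presence filter, and analyses longitudinal community
    change with Bray-Curtis dissimilarity, principal coordinate ordination,
    PERMANOVA and a negative-binomial Wald test for differential abundance
    with Bonferroni control. Includes a synthetic-community generator with
    known ground truth so every stage is testable without sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    Rsamtools,
    igraph,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    vegan,
    DESeq2,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
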