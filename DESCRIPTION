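Package: flsmethylome
Title: Differential Methylation and Pathway Enrichment Analysis for
    Cultured Synoviocyte Methylomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for analysing Illumina-array DNA methylation
    (beta values) of cultured fibroblast-like synoviocytes across disease
    phenotypes and cell passages. Calls differentially methylated loci
    between phenotype groups with Welch's t-test and Storey q-values, maps
    loci into strand-aware promoter windows to label differentially
    methylated genes, performs hypergeometric over-representation analysis
    against KEGG/GO-style gene-set databases with enrichment factors on a
    chip-restricted background, and quantifies signature stability across
    cell passages via Spearman correlation, delta-beta histograms and
    hierarchical clustering. Ships a synthetic-cohort generator emulating
    the statistical structure of array methylomes so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    IRanges,
    S4Vectors,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
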