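Package: snpcart
Title: Candidate-Gene SNP Association with Genetic-Model Selection,
    FDR Control, Cumulative Risk Groups and CART Interaction Trees
Version: 0.1.0
Authors@R: person("Pathway", "Genetics", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A case-control analysis pipeline for candidate-gene SNP panels:
    Hardy-Weinberg quality control in controls, per-SNP logistic association
    under dominant, additive and recessive codings with best-fitting-model
    selection, Benjamini-Hochberg q-values on an LD-pruned SNP set, bootstrap
    internal validation, cumulative unfavorable-genotype risk grouping with
    quartile cut points, and chi-square-driven recursive partitioning (CART)
    for gene-gene interactions. Includes a matched case-control cohort
    simulator with Hardy-Weinberg genotypes, linkage-disequilibrium blocks
    and configurable per-SNP effects so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges
Config/testthat/edition: 3
RoxygenNote: 7.3.3
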