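Package: microscape
Title: Multiscale Diversity, Nestedness and Environment Specificity for Amplicon Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for large multi-study 16S rRNA amplicon
    surveys organised by a structured environment ontology (EMPO). Provides
    the sample-by-tag-sequence observation table data model with filtering,
    rarefaction and environment/study-balanced subsetting; alpha diversity
    (observed richness, Shannon, Chao1, Faith's phylogenetic diversity);
    unweighted and weighted UniFrac with a block-decomposed computation;
    principal coordinates analysis and PERMANOVA; NODF nestedness across
    taxonomic levels with analytic hypergeometric null inference; Shannon
    entropy of environment distributions over taxonomy and phylogenetic
    subtrees with permutation nulls; Laplace and Gaussian upper-envelope
    fits of richness against pH and temperature; mixed-directional FDR
    effect sizes for metadata predictors; abundance-weighted community 16S
    copy number; prevalence-versus-depth profiles and per-tag summary
    cards; and a truth-known synthetic world generator for validating every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    ape,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan,
    picante,
    phyloseq,
    biomformat,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
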