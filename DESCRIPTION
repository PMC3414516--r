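Package: tpsevol
Title: Molecular Evolution Analysis of the Plant Trehalose-6-Phosphate
    Synthase Gene Family
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for molecular-evolution analysis of plant multi-gene
    families, developed around the trehalose-6-phosphate synthase (TPS)
    family of Populus, Arabidopsis and rice. Provides gene-structure
    classification from GFF3 gene models, pairwise protein identity and
    catalytic-residue conservation statistics, counting-based pairwise
    dN/dS estimation (Nei-Gojobori and a YN00-style weighted variant)
    with domain partitioning, Goldman-Yang (GY94) codon substitution
    models with Felsenstein pruning likelihoods and one-ratio/two-ratio
    branch-model likelihood-ratio tests, tree-based duplicate-pair and
    ancestral-lineage analysis, duplication-mechanism and duplicate-fate
    classification, and a codon-alignment simulator so that every stage
    can be validated against data with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    seqinr,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
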