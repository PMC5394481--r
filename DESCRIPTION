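Package: mutassay
Title: Fluctuation-Assay Mutation Rates and Mutation-Accumulation Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative machinery for yeast mutator and antimutator
    studies. Implements the Lea-Coulson (Luria-Delbruck) mutant-count
    distribution with partial plating efficiency, maximum-likelihood
    estimation of the expected number of mutational events per culture,
    profile-likelihood confidence intervals, likelihood-ratio comparisons
    of mutation rates between strains with Bonferroni correction, and
    fold-effect (antimutator effect) ratios. A companion
    mutation-accumulation pipeline filters called variants by depth,
    allele fraction, strain-background SNPs and masked regions, classifies
    mutations into strand-collapsed substitution classes, and computes
    base-composition-normalized frequencies, fractions and genome-wide
    per-division mutation rates. Synthetic-data generators emulate both
    raw-data layers (branching-growth fluctuation cultures with binomial
    plating; heterozygous diploid variant tables with depth and allele
    fraction noise) so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    methods,
    jsonlite,
    Biostrings,
    vcfR,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
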