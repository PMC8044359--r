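Package: tgrm
Title: Trait-Specific Genomic Relationship Matrices for Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Two-stage genomic prediction with trait-specific genomic
    relationship matrices (TGRMs). Marker effects for intermediate
    (endo)phenotypes are estimated with five Bayesian whole-genome
    regression priors (Bayesian ridge, Bayes A, Bayes B, Bayes C-pi,
    Bayesian LASSO) via Gibbs sampling, converted to per-marker weights,
    and used to build weighted genomic relationship matrices that carry
    the genetic signal into an independent population. Single-kernel,
    multi-kernel and multi-trait BLUP models (fitted in the kernel
    eigenbasis) predict a focal trait, and a repeated cross-validation
    harness with a win-rate rule compares models. Includes augmented-
    block mixed-model adjustment with EM-REML, BLUP deregression,
    genotype quality control, and a two-panel simulator for inbred SNP
    panels with LD-block structure and correlated trait architectures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
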