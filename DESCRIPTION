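Package: hamgp
Title: Two-Step Genomic Evaluation of Dry-Cured Ham Weight Loss
Version: 0.1.0
Authors@R: person("hamgp", "maintainers", email = "hamgp@example.org",
    role = c("aut", "cre"))
Description: Tools for a two-step genomic evaluation of ham weight loss
    during dry-curing in a crossbred sib-testing design. Step one fits
    pedigree-based animal models (BLUP, EM-REML variance components) to
    produce pseudo-phenotypes: phenotypes adjusted for fixed effects and
    estimated breeding values with their accuracies. Step two fits five
    Bayesian whole-genome regression models (Bayesian ridge regression,
    BayesA, BayesB, BayesC, Bayesian Lasso) to pseudo-phenotypes of
    crossbred pigs and validates direct genomic values in random
    cross-validation and leave-one-family-out schemes, for crossbreds and
    their purebred sires. A synthetic-data module generates pedigreed
    populations, gene-dropped SNP genotypes and bivariate correlated
    traits (observed and infrared-predicted weight loss) so the whole
    pipeline is testable without proprietary data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
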