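Package: termevol
Title: Phylogenetic Comparative Analysis of Termite Body Size Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood fitting of Gaussian trait-evolution models
    (Brownian motion, directional trend, Ornstein-Uhlenbeck, Pagel's lambda,
    kappa and delta transforms, and a clade-mixed trend+Brownian model) on
    rooted phylogenies that may carry fossil (non-contemporaneous) tips.
    Supports AICc model comparison with Akaike weights, replicated
    one-species-per-genus subsampling, phylogenetic generalized least
    squares under maximum-likelihood branch-length transforms, Bartlett
    variance tests and caste-disparity indices for social-complexity
    analyses, two-state Mk ancestral-state estimation with stochastic
    character mapping, and a synthetic-data generator producing
    fossil-bearing birth-death trees and genus-structured trait tables.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nlme,
    phytools
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
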