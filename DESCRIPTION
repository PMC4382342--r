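Package: shiftscape
Title: Diversification Rate Shifts and Trait-Dependent Speciation on
    Time-Calibrated Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects shifts in net diversification rate on time-calibrated,
    genus-level phylogenies by stepwise AICc search over piecewise
    birth-death models, combining the branching-time likelihood of the
    resolved backbone with a geometric clade-size likelihood for
    unresolved genus tips.  Propagates phylogenetic uncertainty by
    repeating the search over a posterior sample of trees and summarising
    per-clade shift recovery frequencies (sum.prop) and rate dispersion.
    Tests trait-dependent diversification with a binary-state
    speciation-extinction (BiSSE) likelihood with state-specific sampling
    fractions, maximum-likelihood fits, likelihood-ratio tests of the
    equal-speciation constraint, and slice-sampling MCMC with chain
    pooling across trees.  Includes forward birth-death, shifted-regime,
    genus-collapse, pseudo-posterior and state-dependent simulators so
    every stage is testable against planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
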