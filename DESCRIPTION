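Package: orgdist
Title: Exact Equilibrium Distributions for Stochastic Organelle Production
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the four-process stochastic model of organelle copy
    number in single cells (de novo synthesis, fission, first-order decay and
    pairwise fusion). Computes exact limiting count distributions by a
    detailed-balance recurrence, identifies the closed-form limiting laws
    (Poisson, zero-truncated Poisson, negative binomial) with exact mean and
    Fano-factor formulas, simulates single-cell trajectories and cell
    ensembles by fixed-step or event-driven (Gillespie) schemes, decomposes
    organelle production into de novo and fission contributions, and inverts
    observed count moments to rate constants with knockout predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp, jsonlite, stats, utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
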