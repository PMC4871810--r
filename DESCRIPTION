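Package: repfold
Title: Heteropolymer Ising Analysis of Repeat-Protein Equilibrium Unfolding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical-thermodynamic analysis of repeat-protein equilibrium
    unfolding with a one-dimensional heteropolymer Ising (transfer-matrix)
    model. Builds helix-level topologies for consensus tetratricopeptide
    repeat (CTPR) deletion series, computes partition and subpartition
    functions, fraction folded and populations of specific partially folded
    states, globally fits chemical-denaturation curve series to per-helix-class
    intrinsic and interfacial free energies by seeded multi-start nonlinear
    least squares, and simulates re-designed switch constructs that
    preferentially unfold one terminal helix. Includes a synthetic-data
    generator for noisy normalized denaturation curves and chemical-shift
    perturbation utilities for validating terminal-helix unfolding by NMR.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
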