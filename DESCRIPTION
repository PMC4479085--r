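Package: switchscape
Title: Stochastic Switching Analysis of a Positive-Feedback Gene Expression Network
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing a two-state gene expression network with
    positive feedback across slow, intermediate and fast gene-switching
    regimes. Implements the chemical master equation on a truncated
    (gene state x mRNA x protein) lattice with a block-tridiagonal
    steady-state and first-passage solver, exact Gillespie simulation with
    optional tau-leaping, two-layer Gaussian-mixture approximations of the
    stationary landscape in the slow regime, quasi-potential construction by
    the geometric minimum action method in the fast regime, mean switching
    time sweeps over the adiabaticity parameter, and an in-silico
    flow-cytometry sorting experiment that classifies the switching regime
    from protein-level variation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    deSolve,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
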