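Package: epigrn
Title: Stochastic Simulation of the Epigenetic OCT4 Gene Regulatory Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Exact stochastic (Gillespie) simulation of a three-gene
    regulatory network in which the pluripotency factor OCT4 and the
    chromatin modifiers TET1 and JMJD2 are coupled through a five-state
    chromatin modification circuit at each locus (unmodified nucleosomes,
    H3K4me3/ac, CpG methylation, H3K9me3, and both repressive marks).
    Provides the dimensionless parameterisation of the circuit, experiment
    drivers for differentiation and overexpression-driven reprogramming
    studies, first-passage metrics (reactivation efficiency, latency
    distribution and variability), an optional binomial-partitioning
    cell-division mode, and independent validation oracles (exact chemical
    master equation solutions on small state spaces and a mean-field ODE
    reduction).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
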