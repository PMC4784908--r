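Package: selfrep
Title: Self-Replicator Models of Dynamic Microbial Resource Allocation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coarse-grained self-replicator model of bacterial growth in
    which a single allocation parameter divides the precursor flux between
    the metabolic and the gene-expression machinery. Provides steady-state
    analysis and closed-form growth-rate optima, reproduction of the
    empirical growth laws with model fitting to (growth rate, RNA/protein
    ratio) data by differential evolution, numerical solution of the
    biomass-maximizing optimal control problem after a nutrient upshift
    (bang-bang-singular structure, switching-curve estimation), closed-loop
    simulation of simple feedback allocation strategies (nutrient-only,
    precursor-only, on-off), and a reduced ppGpp response surface for
    comparison with the on-off strategy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
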