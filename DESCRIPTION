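Package: sacchsim
Title: Stochastic Simulation of Lignocellulose Saccharification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monomer-resolved stochastic simulation of the enzymatic
    saccharification of a plant cell wall cellulose microfibril surrounded by
    hemicellulose and lignin. The substrate is a three-dimensional lattice of
    polymer chains (a 36-chain quasi-hexagonal cellulose core with up to four
    partially covering outer layers), with configurable composition,
    crystalline regions and a lignin covering-fraction model of branching.
    Digestion by endoglucanase, processive cellobiohydrolase, beta-glucosidase
    and xylanase, together with irreversible enzyme adhesion to lignin, is
    simulated with a Gillespie-type kinetic Monte Carlo algorithm implemented
    in C++. The package also provides the volume and dosage bookkeeping that
    converts batch experimental conditions into simulated enzyme counts,
    conversion and degree-of-polymerization observables, a hybrid
    random/gradient generational fitting procedure for saccharification time
    courses, and seeded synthetic pseudo-experiment generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
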