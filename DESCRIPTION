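Package: nucactin
Type: Package
Title: Two-Compartment Reaction-Diffusion Simulation of Nucleocytoplasmic
    Actin Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates monomeric (G-) and filamentous (F-) actin dynamics in a
    two-dimensional cell built from two static circular compartments, the
    cytoplasm and the nucleus. Thirteen concentration fields (actin, cofilin,
    cofilin-actin, profilin, profilin-actin, phospho-cofilin and a localized
    catalytic factor) evolve under mass-action kinetics, diffusion and
    first-order membrane transfer fluxes across the nuclear envelope, solved
    with a conservative semi-implicit finite-volume scheme on a regular
    Cartesian grid. Includes a constraint-validating parameter model and
    sampler, an equilibration procedure, in-silico knockout experiments for
    the catalysed polymerization and cofilin-phosphorylation pathways, and a
    catalytic-region relocation experiment, with tidy summaries and viridis
    field rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    yaml,
    jsonlite,
    readr,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    rlang,
    generics,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
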