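Package: anaerobead
Title: Quantitative Sustainable Design of Hydrogel-Encapsulated Anaerobic Treatment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multiscale process simulation and sustainability assessment of
    anaerobic treatment of high-strength organic wastewater with
    hydrogel-encapsulated biomass. Couples Anaerobic Digestion Model No. 1
    (ADM1) biokinetics with radial diffusion-reaction in spherical encapsulant
    beads, assembles single- and two-stage fluidized bed, packed bed and UASB
    flowsheets, and integrates them to steady state with a compiled
    right-hand side. Converged scenarios feed parameterized equipment sizing
    and costing, discounted cash flow analysis to a levelized cost of COD
    removal, and an inventory-based life cycle assessment to a GWP100 carbon
    intensity. Three analysis stages support early-stage R&D prioritization:
    discrete design-space enumeration with pairwise normalized indicator
    differences, Latin hypercube Monte Carlo with Kolmogorov-Smirnov
    Monte Carlo filtering, and two-dimensional technology-parameter mapping
    with nested bounded optimization of the carbon intensity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    lhs,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stats,
    utils,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite,
    optparse
Config/testthat/edition: 3
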