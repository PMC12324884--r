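Package: ecoevonet
Title: Eco-Evolutionary Dynamics and Structural Stability of Mutualistic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the coupled ecological and evolutionary dynamics of
    bipartite mutualistic (plant-pollinator) networks. Ecological dynamics
    follow a Lotka-Volterra model with mean-field within-guild competition
    and saturating (Holling type-II) mutualistic benefits, parameterized so
    that a prescribed feasible equilibrium exists. Evolutionary events
    rewire, create or delete mutualistic links one species at a time, with
    an optional biomass-based selection rule and uniform environmental
    perturbations of the intrinsic growth rates. The package also provides
    the structural-stability toolkit for such systems: effective
    interspecific competition from the guild-folded linearization, critical
    competition from mutualistic overlap, the regime distance between the
    two, and critical perturbation amplitudes estimated both analytically
    and by Monte-Carlo extinction experiments, together with bipartite
    topology metrics (connectance, NODF and null-normalized NODF, ecological
    overlap, degree heterogeneity, assortativity), factorial experiment
    drivers, and tidy outputs with ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    igraph,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
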