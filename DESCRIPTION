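Package: nanosorb
Title: Lennard-Jones Adsorption of Rigid Drug Molecules on Carbon Nanocarriers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hybrid discrete-continuous Lennard-Jones modelling of small-molecule
    drug adsorption on idealized carbon nanocarriers (infinite flat graphene
    sheet and spherical C60 fullerene). Provides closed-form atom-plane and
    atom-sphere interaction energies, rigid-body pose handling, a
    single-objective evolutionary minimizer over the 5n pose variables with
    multi-seed search and grouping of distinct stable configurations, and the
    geometric descriptor suite (interplanar distance, incline, rotation and
    tilt angles, angular separation) used to characterize pi-stacked
    equilibrium configurations. Includes brute-force lattice-sum and
    quadrature oracles that validate the continuum formulas without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
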