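Package: yeastcc
Title: Stochastic Simulation of the Budding-Yeast Cell-Cycle Control Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds the mass-action reaction network of the budding-yeast
    (Saccharomyces cerevisiae) cell-cycle control system -- multisite
    phosphorylation chains, stoichiometric inhibitor complexes, APC/Cdc20
    affinity ladder, regulated and constitutive gene expression -- and
    simulates it either deterministically (mass-action ODEs with event
    detection and symmetric division) or exactly by Gillespie's stochastic
    simulation algorithm inside an exponentially growing, asymmetrically
    dividing cell. A lineage-tracking "computational culture" scheduler grows
    whole pedigrees of cells, a mutant catalog applies genotype edits to the
    wild-type network, and single-cell statistics (coefficients of variation,
    size-control regressions, Poisson and two-component-Poisson mRNA fits,
    number-doubling-time estimation, Sic1 decay fitting) reproduce
    population-level variability analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
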