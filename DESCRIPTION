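Package: emkin
Title: Ensemble-Modeling Kinetics and Constraint-Based Analysis of Fermentation Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Two-layer modeling of anaerobic central metabolism in the style used
    for Clostridium thermocellum. A stoichiometric layer provides flux balance
    analysis, flux variability analysis, yield-range calculations and a
    cycle-elimination constraint that removes thermodynamically infeasible
    cycles while letting alternate-cofactor isozymes stay simultaneously
    active. A kinetic layer decomposes net reactions into elementary
    mass-action steps, samples ensemble parameter sets anchored to a reference
    steady state, fits them to multi-mutant fermentation data with a genetic
    algorithm, and runs cross-validation, enzyme-level perturbation scans and
    robustness analysis. A synthetic-data module generates ground-truth
    branched fermentation networks and noisy mutant libraries so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    deSolve,
    xml2,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
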