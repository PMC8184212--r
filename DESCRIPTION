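Package: crossfeed
Title: Dynamics and Assay Estimators for Obligate Metabolite Cross-Feeding Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and measures two-strain microbial mutualisms in which each
    strain releases a costly metabolite the partner requires. Provides Moser
    (Hill-type Monod) growth kinetics, ODE simulations of lysine-limited
    chemostats, closed cross-feeding communities and two-genotype competition,
    closed-form steady-state theory (the community growth rate as the geometric
    mean of the two strains' exchange ratios), estimators for the standard
    assays (sliding-window log-slope growth rates, Moser parameter fits,
    bead-calibrated flow-cytometry densities, yield-based bioassay inversion,
    chemostat exchange ratios, community steady-state growth rates, generation
    counting), the partner growth-rate prediction from an exchange-ratio fold
    change with replicate-based confidence intervals, and seeded synthetic-data
    generators with ground-truth sidecars for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'crossfeed-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'moser.R'
    'steady-state.R'
    'simulate.R'
    'growth-rate.R'
    'moser-fit.R'
    'steady-detect.R'
    'exchange-ratio.R'
    'cytometry.R'
    'bioassay.R'
    'community-rate.R'
    'generations.R'
    'inference.R'
    'synthetic.R'
    'io.R'
    'pipeline.R'
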