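Package: omegaflux
Title: Functional Interpretation of Metabolomic Time Series via Weighted
    Smoothing Splines and Interaction-Ratio Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits inverse variance-weighted cubic smoothing splines to
    replicate metabolite concentration time courses, derives metabolic
    functions (first time derivatives of the smoothed concentrations) and
    their dynamics (second derivatives), connects them through a binary
    interaction matrix built from reaction-network stoichiometry, and
    computes the time-resolved ratio statistic omega(a->b,t) that flags
    time points of perturbed biochemical dependency between metabolite
    pools. Includes a mass-action ODE simulator with replicate noise for
    generating benchmark data, reaction-list and SBML network import, and
    an end-to-end pipeline with command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'network.R'
    'omega.R'
    'pipeline.R'
    'simulate.R'
    'spline.R'
    'timeseries.R'
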