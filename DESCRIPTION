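Package: pascore
Title: Pathway Activation Scoring from Gene-Expression Data with
    Kinetic-Model Importance Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative scoring of intracellular signaling pathway
    activation from genes-by-samples expression matrices. Each pathway
    member carries a signed activator/repressor role; the pathway
    activation strength (PAS) of a pathway in a case sample is the
    role-weighted sum of log10 case-to-norm expression ratios, optionally
    gated by a beyond-tolerance-interval filter and weighted by per-gene
    importance factors. Importance factors are derived from mass-action
    kinetic models of the pathway, either from the time-averaged
    log-sensitivity of the effector trajectory to total protein
    concentrations or from the stiffest eigendirection of the Hessian of
    a least-squares effector-fit objective (sloppiness analysis). A
    stochastic robustness module re-scores pathways under random
    log-normal per-gene weights, and a synthetic-data module generates
    pathway catalogs, case/control expression cohorts with planted
    signals, and toy signaling cascades for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
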