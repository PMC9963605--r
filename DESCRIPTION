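Package: pkshape
Title: Shape-Sensitive Pharmacokinetic Metrics and Model-Predicted
    Steady-State Bioequivalence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing whether two prolonged-release oral
    formulations that look bioequivalent after a single dose will remain
    bioequivalent at steady state. Implements non-compartmental analysis
    with alternative curve-shape metrics (concentration at the end of the
    dosing interval, paired partial AUCs at arbitrary cut-offs, half-value
    duration), average-bioequivalence statistics for the 2x2 crossover
    (geometric mean ratio, 90% confidence interval, intra-subject CV), an
    analytic transit-compartment absorption model with one-compartment
    disposition, empirical-Bayes individual parameter estimation,
    superposition-based steady-state prediction, prediction-corrected
    visual predictive checks, and a synthetic crossover-study generator
    emulating a desvenlafaxine 100 mg prolonged-release bioequivalence
    trial.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
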