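Package: lcsmodel
Title: Cost-Effectiveness Modelling of Low-Dose CT Lung Cancer Screening
Version: 0.1.0
Authors@R: person("Model", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A decision-analytic model for evaluating the cost-effectiveness
    of a national low-dose computed tomography (LDCT) lung cancer screening
    programme against no screening, from a healthcare payer perspective.  A
    screening decision tree (eligibility, uptake, annual rounds, stage
    allocation, missed individuals) feeds a stage-stratified state-transition
    Markov cohort model run at three-month cycles with parametric survival
    extrapolation from summary anchors, background mortality from a life
    table, full cost and utility accounting with discounting, and
    deterministic, probabilistic and scenario sensitivity analysis
    (tornado diagrams, PSA, CEAC).  Ships a synthetic screening-outcome
    generator calibrated to published stage-shift targets so the whole
    pipeline is testable without restricted trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
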