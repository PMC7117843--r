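Package: fracturetwin
Title: Virtual-Twin and FRAX-Based Estimation of Long-Term Antifracture
    Efficacy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the long-term antifracture efficacy of a treatment
    when the extension phase of a trial lacks a control arm.  Observed
    10-year Kaplan-Meier cumulative incidence of major osteoporotic and hip
    fractures is compared with (a) a counterfactual "virtual twin" placebo
    cohort built from a Poisson fracture-rate model with a log person-time
    offset, calibrated on the placebo (crossover) arm of the core trial,
    with subject-level percentile-bootstrap confidence intervals, and (b)
    externally supplied FRAX-style 10-year fracture probabilities.  Includes
    a synthetic two-arm trial generator with known ground truth so every
    estimator is testable without patient-level trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
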