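Package: copdcea
Title: Cost-Utility Modelling of Rapid Respiratory Panel Testing in COPD
    Exacerbations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A configuration-driven cost-utility analysis of point-of-care
    multiplex respiratory panel testing to guide antibiotic prescribing in
    acute exacerbations of chronic obstructive pulmonary disease (COPD).
    Couples a short-run decision tree (treatment rounds, hospital admission,
    recovery or death) to a lifetime Markov cohort model over exacerbation
    severity and GOLD stage, with half-cycle discounting and age-specific
    all-cause mortality. Provides incremental cost-effectiveness and net
    monetary benefit calculus, one-way deterministic sensitivity analysis,
    break-even price search, seed-reproducible probabilistic sensitivity
    analysis with cost-effectiveness acceptability curves, and two procedures
    for attaching antimicrobial-resistance costs to antibiotic prescribing:
    a per-prescription resistance penalty and resistance-trajectory-scaled
    annual cost savings. Inputs not available as published point estimates
    are generated synthetically with explicit provenance flags.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
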