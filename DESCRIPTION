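Package: crmcompare
Title: Operating Characteristics of the Two-Stage CRM and 3+3 Dose-Escalation Designs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation engine for phase 1 oncology dose-finding designs. Implements
    the two-stage extended continual reassessment method (CRM) with a one-parameter
    Bayesian logistic toxicity model and pluggable prior skeletons, the 3+3 design as
    a decision state machine with an exact enumeration oracle for its operating
    characteristics, true dose-toxicity scenario definitions derived from four phase 1
    oncology trials plus theoretical curves, reproducible Bernoulli toxicity outcome
    streams, a Monte-Carlo replicate driver, and summarisation of selection accuracy
    (correct, underestimated, overestimated, not determined maximum tolerated dose).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
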