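Package: cdk46cea
Title: Markov Cohort Cost-Effectiveness Model for CDK4/6 Inhibitors in
    Advanced Breast Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A within-cycle-corrected Markov cohort state-transition model
    comparing the three CDK4/6 inhibitors (palbociclib, ribociclib and
    abemaciclib, each combined with letrozole) against letrozole monotherapy
    in first-line HR+/HER2- advanced breast cancer, from the Qatari
    healthcare-payer perspective.  Provides the three-state (progression-free
    with dose tiers, progressed disease, death) cohort engine with half-cycle
    correction and discounting, probability/rate calculus for transition
    inputs, incremental cost-effectiveness analysis with dominance
    classification and willingness-to-pay decisions, one-way deterministic
    sensitivity analysis with conclusion-flip threshold search and tornado
    outputs, a synthetic-scenario generator for property testing, and report
    writers with a thin command-line wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
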