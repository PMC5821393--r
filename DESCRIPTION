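Package: paniccea
Title: Cost-Effectiveness Modelling of Early Intervention for Subthreshold Panic Disorder
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Four-state Markov cohort model (panic-free, subthreshold panic
    disorder, panic disorder, death) for evaluating the addition of a
    CBT-based early intervention for subthreshold panic disorder to usual
    care for panic disorder from a societal perspective. Provides
    intervention uptake/adherence logic, societal costing with differential
    discounting of costs and effects, probabilistic sensitivity analysis
    with cost-effectiveness acceptability curves, one-way deterministic
    sensitivity scenarios, and an individual-level microsimulation used to
    validate the cohort engine by Monte Carlo.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
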