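Package: dempath
Title: Cohort Markov Modelling of Dementia Care Pathways for Early
    Health Technology Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A cohort Markov state-transition model of the dementia care
    pathway for early cost-effectiveness analysis of care technologies.
    Nine living states combine dementia severity (mild, moderate, severe)
    with care setting (no formal care, home care, institutional care),
    plus absorbing death. Intervention strategies act through
    state-value deltas (utility, caregiving hours, costs) and relative
    risks on care transitions, with short-term pilot evidence
    extrapolated via surrogate-outcome links and explicit persistence
    assumptions. Includes discounted QALY and societal cost accounting,
    ICER/NMB/CEAC summaries, probabilistic sensitivity analysis, tornado
    and scenario analyses, synthetic parameter fixtures, and a YAML/JSON
    configuration surface with a command-line runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
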