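Package: nmrisk
Title: Combined FMEA and Fault Tree Risk Analysis for Nuclear Medicine Workflows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for proactive patient-safety risk assessment in nuclear
    medicine diagnostic and therapeutic workflows. Implements failure modes
    and effects analysis (FMEA) with ten-step severity/occurrence/
    detectability rating scales and risk priority numbers (RPN), proactive
    and reactive barrier modelling with multiplicative miss probabilities,
    automatic conversion between FMEA registers and fault trees via the
    failure modes and effects summary (FMES) grouping, undetected
    adverse-event rate computation with per-year annualization, weighted
    multi-rater consensus scoring, throughput-weighted cross-workflow
    ranking, nuclear-medicine process templates, a synthetic questionnaire
    generator, and a Monte Carlo simulator used as an independent check of
    the analytic rates. Includes project-file persistence (JSON/YAML),
    CSV/markdown report export, DOT fault-tree export and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
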