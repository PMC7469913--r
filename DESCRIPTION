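Package: crmdose
Title: Model-Guided Dose-Escalation Designs for Phase I Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conduct and simulate phase I dose-finding trials with the
    continual reassessment method (Bayesian or maximum-likelihood), its
    time-to-event extension (TITE-CRM), escalation with overdose control
    (EWOC), and time-to-event EWOC. Provides skeleton calibration by the
    indifference-interval construction, posterior computation by
    deterministic quadrature, trial conduct with pending-outcome handling,
    an audit trail and JSON persistence, and Monte-Carlo evaluation of
    operating characteristics (distribution of the recommended maximum
    tolerated dose and per-level patient allocation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
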