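Package: jitair
Title: Just-in-Time Adaptive Intervention Engine and Trial Simulator for
    Smoking Cessation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a just-in-time adaptive intervention (JITAI) decision
    engine for smoking cessation built on ecological momentary assessment
    (EMA): prompt scheduling over a 35-day quit-attempt window, weighted
    lapse-risk scoring from momentary self-reports, high-risk classification,
    trigger-tailored message selection with nicotine-gum prompting, and
    engagement-event logging.  A companion synthetic-cohort simulator
    generates three-arm trial datasets (Likert EMA items, per-participant
    compliance, a risk-linked lapse process, dropout, carbon-monoxide
    verified visits) so the engine and the trial-statistics layer --
    intent-to-treat abstinence tables, chi-square tests across arms, one-way
    ANOVA reconstructed from group summaries, compliance-tier compensation --
    are fully testable without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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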