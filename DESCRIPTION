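Package: sepsisrl
Title: Offline Reinforcement Learning for Corticosteroid Dosing Policies in Sepsis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for deriving and evaluating
    corticosteroid dosing policies for septic ICU patients from retrospective
    electronic health record data. Includes a synthetic ICU event generator
    with a known ground-truth decision process, operationalized Sepsis-3
    cohort extraction (daily SOFA scoring, suspected-infection detection,
    exclusion rules, septic-shock flagging), 24-hour feature binning with
    leakage-free imputation and normalization, Markov-decision-process
    trajectory construction over a five-level hydrocortisone-equivalent dose
    action space, a temporal-difference actor-critic learner, high-confidence
    off-policy evaluation via truncated importance sampling with
    empirical-Bernstein lower bounds, and explainability through layer-wise
    relevance propagation and a random-forest behavior clone of the clinician
    policy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    ranger,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
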