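Package: pavca
Title: Scoring, Phenotyping and Simulation for Pavlovian Conditioned
    Approach Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative analysis of cue-motivated behavior in
    the sign-tracker/goal-tracker rat model. Converts trial-level operant
    event logs into the six standard Pavlovian conditioned approach (PavCA)
    session measures, computes the PavCA composite index (response bias,
    probability difference, latency difference), classifies sign-, goal-
    and intermediate trackers under configurable threshold regimes, builds
    counterbalanced treatment-group assignments, scores conditioned
    reinforcement (FR1) sessions via the incentive value index, normalizes
    microdialysis fraction series to percent change from baseline and
    quantifies dopamine-behavior coupling by linear regression. An
    agent-based generator simulates complete cohorts (PavCA sessions on a
    variable-time schedule, conditioned reinforcement sessions, dialysis
    series coupled to behavior) so every stage of the pipeline is testable
    without animal data. Inference utilities include Tukey 1.5 IQR outlier
    reports, Cohen's d, pooled t-tests, balanced two-way ANOVA and a
    permutation test for treatment-by-session interactions, with
    simulation-based power estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
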