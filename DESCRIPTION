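Package: staggerdid
Title: Staggered Difference-in-Differences Pipelines for Health Policy
    Quasi-Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating staggered regional policy rollouts on
    per-person binary health outcomes with linear probability models on the
    per-1,000 scale. Implements the staggered two-way interaction
    difference-in-differences estimator with cluster-robust inference,
    relative-time (event-study) parallel-trend diagnostics, non-parametric
    permutation placebo tests that reassign pilot regions and adoption
    timing, entropy balancing solved through its exponential-tilting dual,
    logistic propensity scores with nearest-neighbour caliper matching,
    entropy-weight composite pollution indices, triple-interaction
    moderation models, subgroup analyses with Chow tests, and a synthetic
    cohort generator that emulates a biennial ageing-cohort panel so every
    estimator is testable by parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    MASS,
    sandwich,
    arrow,
    optparse
Config/testthat/edition: 3
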