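Package: leapfrog
Title: Simulation and Analysis of Exploratory Choice in the Leapfrog Task
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to simulate and analyse two-option "leapfrog" reward
    environments used to study the explore-exploit tradeoff across the
    life span. Provides the reward environment in two hazard regimes
    (sequentially independent jumps and a ramping, history-dependent
    hazard), generative choice agents (reflexive, ideal reflective, and
    gambler's-fallacy reflective belief models), derivation of
    explore/exploit labels and exploration hazard curves from trial-level
    choice data, per-participant strategy classification by BIC model
    comparison, trial-wise mixed-effects logistic regressions and group
    contrasts, and a synthetic cohort generator so the full behavioural
    pipeline can be exercised end to end without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    lme4,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
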