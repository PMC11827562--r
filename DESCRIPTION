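Package: voiplan
Title: Resource-Rational Valuation of Non-Instrumental Information
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and hierarchical Bayesian analysis of willingness to
    pay for non-instrumental information under a resource-rational model of
    planning. Provides the deterministic value-of-information core (utilities
    of obtaining information, planning in uncertainty, and leisure; ordered
    logistic mapping of the value of information onto 5-point Likert
    responses), a synthetic-study generator (truncated-normal agent
    populations on a 30-scenario design grid, questionnaires with planted
    trait-anxiety factor structure), a No-U-Turn sampler for the hierarchical
    planning model and its reduced variants, Pareto-smoothed importance
    sampling leave-one-out model comparison, posterior predictive checks and
    parameter-recovery reports, Bartlett factor scoring of the STAIT and
    STICSAT inventories, mixed-effects ordinal and linear association
    analyses, and a command-line pipeline tying the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    MASS
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
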