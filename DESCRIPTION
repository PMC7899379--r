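Package: rlbias
Title: Spurious Group Differences in Model-Based fMRI from
    Reinforcement-Learning Model Misfit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies how misfit of reinforcement-learning model
    parameters (e.g., a common learning rate applied to heterogeneous
    subjects) and model misspecification (e.g., omitting a forgetting
    process) bias the regression coefficients ("beta values") of
    model-derived regressors in trial-wise GLM analyses of neural
    signals.  Provides closed-form expectations and variances of beta
    estimates for the Rescorla-Wagner model under a fixed reward
    probability, standardized effect sizes and noncentral-t power for
    one- and two-sample tests, maximum-likelihood fitting of standard
    and forgetting Q-learning models, and seeded simulation pipelines
    that reproduce the group-comparison, dimensional, heterogeneity and
    misspecification experiments these statistics describe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
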