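Package: trialmi
Title: Multiply Imputed Analysis of Three-Arm Randomized Dietary Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A complete statistical pipeline for three-arm parallel-group
    randomized trials with continuous outcomes measured at baseline and
    follow-up: stratified permuted-block randomization with co-randomized
    household pairs, a synthetic-trial generator with missing-at-random
    outcome blanking, multiple imputation by chained equations with
    predictive mean matching, per-imputation baseline-adjusted ANCOVA pooled
    by Rubin's rules with a multivariate Wald omnibus test and gatekept
    pairwise contrasts, Shapiro-Wilk routing to a nonparametric branch
    (covariate-adjusted residuals, Kruskal-Wallis, bootstrap-then-impute
    percentile intervals for adjusted median differences, Hodges-Lehmann
    per-protocol estimation), regression-based causal mediation with
    proportion mediated, and sample-size/power design calculations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    emmeans
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
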