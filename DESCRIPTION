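Package: swmediate
Title: Bootstrap Mediation Analysis for Stepped-Wedge Cluster Randomized Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Product-of-coefficients mediation analysis for stepped-wedge cluster
    randomized trials with repeated questionnaire measures. Fits paired
    random-intercept linear mixed models (treatment to mediator, mediator to
    outcome), estimates indirect effects as the product of path coefficients,
    and derives percentile confidence intervals and sign-crossing p-values from
    a cluster-stratified nonparametric bootstrap over participant trajectories.
    Includes multivariate (simultaneous-mediator) and sensitivity variants,
    time-lagged mediator models with participant and cluster random intercepts,
    baseline descriptive tables with Benjamini-Hochberg correction, and a
    synthetic trial generator that emulates the stepped-wedge design so every
    inferential stage can be exercised without access to trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils,
    parallel
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
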