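Package: glmcb
Title: Generalized Linear Models with the Cluster Bootstrap
Version: 0.1.0
Authors@R: person("glmcb", "developers", role = c("aut", "cre"),
    email = "glmcb@example.org")
Description: Marginal-model inference for clustered and longitudinal data
    using generalized linear models with the balanced cluster bootstrap.
    Whole clusters (e.g., all repeated measurements of a subject) are
    resampled so that every cluster appears exactly B times across the B
    bootstrap samples. Parametric, percentile and bias-corrected and
    accelerated (BCa) confidence intervals are provided, the latter using
    a leave-one-cluster-out jackknife for the acceleration factor.
    Bootstrap samples in which the GLM cannot be fitted (separation,
    constant response, dropped factor levels) are tracked and can be
    reconstructed for inspection. A built-in Monte Carlo module evaluates
    bias, type-I error, power and coverage of the procedure under a
    linear mixed model generating design.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    parallel,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
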