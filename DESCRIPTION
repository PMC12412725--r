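Package: lsjoint
Title: Location-Scale Joint Models for Longitudinal Markers and Competing Risks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits shared-random-effect joint models in which a linear mixed
    model with a subject-specific, time-dependent residual standard deviation
    (a location-scale mixed model) is linked to cause-specific proportional
    hazard models for competing events through the marker's current value,
    current slope and current residual standard deviation. Estimation is by
    maximum likelihood with quasi-Monte-Carlo integration over the random
    effects (Sobol sequences), 15-point Gauss-Kronrod quadrature for
    cumulative hazards and a Marquardt-Levenberg optimizer with inflated
    Hessian and relative-distance-to-maximum convergence criterion. The
    package also provides empirical-Bayes random-effect modes, dynamic
    individual risk predictions with Monte-Carlo confidence bands, a
    simulator for competing-risk location-scale designs and replication-level
    performance summaries (bias, empirical and asymptotic standard errors,
    coverage).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    lme4,
    MASS,
    generics,
    Rcpp,
    rlang,
    splines,
    stats,
    survival,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
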