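Package: prrglm
Title: Partial Reduced-Rank Multivariate Generalized Linear Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum likelihood estimation and asymptotic inference for
    multivariate generalized linear models in which the coefficient block of a
    chosen subset of predictors is restricted to low rank. Fits the
    unrestricted model by Fisher scoring and the rank-restricted model by
    alternating maximization over a matrix factorization, and provides the
    plug-in asymptotic covariance of the restricted estimator obtained by an
    oblique projection of the unrestricted information, entrywise standard
    errors, Wald tests and confidence intervals for every entry of the
    rank-restricted coefficient matrix, case-resampling bootstrap variance
    estimates, and AIC-based rank selection. Includes multinomial-logit,
    Poisson-log and Gaussian families, a synthetic-data generator for
    simulation studies, and broom-style tidiers with ggplot2 diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
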