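Package: melsmsim
Title: Simulation and Estimation for Mixed-Effects Location-Scale Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how mixed-effects location-scale models (MELSM) and
    ordinary linear mixed models behave under variance heterogeneity and model
    misspecification. Provides a generator for heteroscedastic longitudinal data
    (random intercepts and slopes on both the mean and the log residual standard
    deviation, Gaussian or Student-t random effects, non-linear time trends), an
    estimation engine built on the marginal likelihood via adaptive Gauss-Hermite
    quadrature (maximum likelihood and adaptive Metropolis posterior sampling),
    replication-study metrics (bias, interval coverage, interval width, sampling
    and estimated standard errors), and a registry of misspecification scenarios
    with a paired replication runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    glmmTMB,
    jsonlite,
    lme4,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
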