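Package: critlearn
Title: Trial-by-Trial Criterion Learning Models for Perceptual Categorization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, model fitting, and model-free analysis of decision-criterion
    learning in orientation-categorization tasks. Generates synthetic covert- and
    overt-criterion sessions under static category means or a Gaussian random walk,
    implements five trial-by-trial observer models (ideal Bayesian with parameter
    marginalization, Bayesian model selection by running means, exponentially
    weighted moving average, Kalman filter, delta-rule reinforcement learning, and
    limited memory), fits them by adaptive Metropolis-within-Gibbs MCMC with
    split-chain convergence diagnostics and DIC, compares models per observer and at
    the group level by random-effects Bayesian model selection (exceedance
    probabilities), and provides lagged-regression, cross-correlation, psychometric
    and matching-noise analyses of the simulated behavior.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
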