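Package: whitepox
Title: Bayesian Space-Time Modelling of White-Pox Disease on Acropora palmata
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Spatio-temporal analysis of white-pox disease presence/absence on
    mapped elkhorn coral (Acropora palmata) colonies. Fits a latent-Gaussian
    binomial model with a Matern spatial field evolving under first-order
    autoregressive dynamics and eight ecological covariates, using a nested
    Laplace approximation (inner Gaussian approximation over the latent field,
    outer grid integration over hyperparameters). Includes covariate
    engineering for disease-history and distance predictors, kernel-smoothed
    intensity mapping of the colony point pattern, a synthetic survey-panel
    generator with known ground truth, and simulation-based parameter-recovery
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    jsonlite
Config/testthat/edition: 3
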