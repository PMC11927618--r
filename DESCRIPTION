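Package: memfp
Title: Splitting Probabilities and First-Passage Observables for
    Non-Markovian Gaussian Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to predict and measure which of two absorbing targets a
    random walker with memory reaches first.  Implements a nonperturbative
    self-consistent theory of splitting probabilities for one-dimensional
    isotropic Gaussian processes with stationary increments, driven entirely
    by the mean-squared-displacement function of the process; exact
    circulant-embedding and normal-mode samplers for fractional Brownian
    motion, bidiffusive, viscoelastic and Rouse-chain dynamics; a
    large-volume extension to higher dimensions built on time-integrated
    propagator differences; and a single-particle-tracking analysis pipeline
    (MSD estimation and fitting, Gaussianity and drift diagnostics,
    empirical splitting probabilities and post-first-passage mean
    trajectories).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
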