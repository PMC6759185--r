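Package: perisacc
Title: Time-Varying Encoding Models of Perisaccadic Neural Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits and analyses millisecond-resolution, time-varying
    point-process encoding models of visual neurons around saccadic eye
    movements.  Implements a sparse-variable Poisson generalized linear
    model whose spatiotemporal stimulus kernels are tensor products of
    quadratic B-splines over time and delay (the S-model), a factorization
    of the fitted kernels into receptive-field, future-field and
    saccade-target skew-Gaussian modulatory sources plus a fixation kernel
    (the F-model), and a resampled aggregate of factorized fits (the
    A-model).  Includes pseudorandom balanced probe-grid experiment
    generation, conditional-Poisson spike simulation with refractory
    feedback, classification of perisaccadic suppression and remapping
    effects, prevalence maps, dichotomous model-vs-data agreement metrics,
    robust perisaccadic-to-fixation performance ratios, and ROC-based
    spatiotemporal stimulus detectability analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
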