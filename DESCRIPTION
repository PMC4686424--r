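Package: raceddm
Title: Race Diffusion Models of Reactive and Proactive Inhibitory Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and fitting of race-diffusion models of action
    stopping. A gain-modulated drift-diffusion execution process generates
    go responses; stopping is modelled either by a dependent braking
    process that inherits the execution state at the stop-signal delay, by
    an independent racing accumulator, or by an interactive suppression
    signal subtracted from the execution process. Includes stop-signal
    (reactive) and cued go-probability (proactive) task designs, summary
    statistics (response probabilities, RT quantiles, logistic points of
    subjective equality), Maritz-Jarrett weighted chi-square cost
    functions, a two-stage basin-hopping plus Nelder-Mead fitting
    protocol with AIC/BIC model comparison, a cumulative-sum BOLD
    predictor, and synthetic multi-subject cohort generation for
    parameter- and model-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
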