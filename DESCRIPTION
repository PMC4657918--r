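Package: flywalk
Title: Fluctuation-Driven Neural Network Models of Fly Locomotor Bouts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how ongoing activity fluctuations in small
    action-selection circuits shape the timing of walking bouts in Drosophila.
    Generates synthetic intermittent-locomotion datasets, classifies speed
    traces into walking and stationary bouts with a hysteresis threshold,
    summarises bout-duration statistics as weighted variable-bin-width
    histograms, simulates continuous-time recurrent neural network (CTRNN)
    models driven by Gaussian, power-law or Ornstein-Uhlenbeck fluctuations,
    fits model parameters to bout statistics by particle swarm optimisation,
    and characterises fitted models with dynamical-systems analysis
    (equilibria, stability, trajectory density, switching class, Lyapunov
    spectra and Kaplan-Yorke dimension).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma
Config/testthat/edition: 3
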