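Package: itdtrack
Title: Bayesian Prediction of Moving Sound-Source Direction and Its
    Population-Vector Readout
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling auditory tracking of a moving sound source
    from interaural time difference (ITD) sequences, as in barn-owl sound
    localization. Implements the linear-Gaussian generative model of source
    direction and angular velocity, Bayes-optimal n-step-ahead prediction by
    Kalman filtering and by particle filtering with resampling, a non-uniform
    population code whose firing rates equal a scaled ratio of the predictive
    posterior to the proposal density of preferred stimuli, population-vector
    decoding from deterministic rates or Poisson spike counts, receptive-field
    shift analysis for constant-velocity stimuli, and an evaluation harness
    comparing the population-vector estimate with the Bayesian prediction over
    a grid of stimulus conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
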