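Package: semwta
Title: Spike-Based Expectation Maximization in Winner-Take-All Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of stochastic spiking winner-take-all
    (WTA) circuits whose weight-dependent spike-timing-dependent plasticity
    (STDP) and intrinsic excitability plasticity fit a multinomial mixture
    model to high-dimensional spike inputs, a principle known as spike-based
    Expectation Maximization (SEM). Provides the spiking network core with
    exponential stochastic firing, rectangular and alpha-kernel EPSP models,
    simple and continuous-time STDP rules with adaptive (variance-tracking)
    learning rates, a common-inhibition model with reset impulse and
    Ornstein-Uhlenbeck background noise, population-code spike encoders, an
    exact batch Expectation-Maximization oracle for the equivalent
    multinomial mixture model, synthetic input generators (Gaussian-blob
    images, oriented bars, frozen Poisson spatio-temporal spike patterns),
    and reproducible runners for hidden-cause discovery,
    orientation-selectivity and spike-pattern detection experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
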