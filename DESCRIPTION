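Package: phasenoise
Title: Dynamic Noise Inference in Time-Varying Cardio-Respiratory Phase Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates weakly coupled cardiac and respiratory phase oscillators
    under controlled time-varying breathing protocols (free, ramp, sine,
    aperiodic), verifies protocol following by continuous Morlet wavelet
    transform and ridge extraction, infers the stochastic phase model by
    adaptive dynamical Bayesian inference over sequential windows (Fourier
    coupling basis, recursive posterior updates, prior propagation for
    time-varying parameters), and summarises the inferred 2x2 dynamic-noise
    intensity matrix across subjects and breathing conditions with
    Holm-Bonferroni corrected pairwise comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
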