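Package: replaynet
Title: Assembly-Sequence Replay in Balanced Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and mean-field analysis of memory replay in balanced
    recurrent networks of conductance-based leaky integrate-and-fire neurons.
    Builds sparse random networks with embedded Hebbian assembly sequences
    (feedforward, symmetric, or continuous wiring), balances them with a
    homeostatic inhibitory spike-timing-dependent plasticity rule, and runs
    cued-replay, spontaneous-activity, and linear-track protocols. Provides
    the accompanying measurement battery (Gaussian-smoothed population rates,
    replay-quality scoring, spontaneous-replay counting, spike-train
    irregularity and synchrony, pulse-packet state portraits) and closed-form
    or numeric theory: the effective feedforward amplification factor and its
    critical line, conductance-based response times, a diffusion-approximation
    estimate of the population transfer-function slope, and network
    size-scaling laws.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
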