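Package: ssvepnmm
Title: Multi-Dynamic Coupled Neural Mass Modelling of Steady-State
    Visual Evoked Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation of steady-state visual evoked potential (SSVEP)
    electroencephalography with Jansen-Rit-type neural mass models. Each
    cortical region carries three parallel synaptic kernel banks (delta,
    alpha, gamma) merged by weights on the unit simplex, and two regions
    (occipital and parietal) are coupled bidirectionally through a
    de-meaned sigmoid firing-rate pathway and a cross-regional synaptic
    encoder. Includes FFT band-energy identification of the oscillator
    weights, particle swarm optimization of coupling and noise parameters
    against a target power spectrum, time-domain consistency metrics,
    stochastic signal-augmentation operators, a stimulus-locked SSVEP
    surrogate generator, and a command-line interface for the full
    simulate-classify-decode pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
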