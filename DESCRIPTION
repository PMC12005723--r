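Package: pulseDDM
Title: Joint Neural-Behavioral Drift-Diffusion Models for Pulse-Based
    Evidence Accumulation
Version: 0.1.0
Authors@R:
    person("pulseDDM", "Developers", email = "pulseddm@example.org",
           role = c("aut", "cre"))
Description: Fits bounded drift-diffusion (evidence accumulation) models
    jointly to spike trains and binary choices from pulse-based (auditory
    click) decision tasks. The latent accumulator is driven by sensory-
    adapted click inputs and propagated with a discretized Fokker-Planck
    (Markov transition) operator with absorbing bounds. Spike counts are
    modeled with Poisson or negative-binomial likelihoods through softplus
    tuning curves with radial-basis-function baselines; choices follow a
    threshold rule with lapses. Provides maximum-likelihood fitting with
    Laplace confidence intervals, latent posterior decoding, model
    comparison (joint, choice-only, independent-noise), change-of-mind
    detection, and a complete synthetic-session generator for parameter
    recovery studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
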