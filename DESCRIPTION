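Package: hfbmtrack
Title: MSD, Ergodicity and Ageing Analysis of Single-Particle Tracks with
    Heterogeneous FBM Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistics for two-dimensional single-particle tracking data in
    which trajectory durations are random, as for endosomes imaged in a finite
    focal volume. Provides ensemble-averaged, time-averaged and
    ensemble-time-averaged mean squared displacement estimators with
    censoring-aware averaging, ageing (delayed-start) and duration-conditioned
    variants, power-law fits with optional additive localization-error offset,
    ergodicity-breaking statistics (tMSD amplitude scatter, the EB parameter,
    generalized-Gamma fits, single-trajectory ergodicity and mixing
    functionals), and an exact circulant-embedding simulator of
    ensemble-heterogeneous fractional Brownian motion with duration-dependent
    diffusivity, used to show how ensemble heterogeneity produces spurious
    long-time subdiffusion and apparent statistical ageing in ergodic data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
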