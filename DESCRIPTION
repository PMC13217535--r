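Package: timbreIC
Title: Spectral-Peak Coding Analysis for Inferior Colliculus Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Synthesis of harmonic complex "synthetic timbre" stimuli with
    triangular spectral envelopes, seeded simulation of inferior-colliculus
    (IC)-like neurons as inhomogeneous Poisson processes, and the analyses
    used to study spectral-peak (timbre brightness) coding in IC: average
    rate profiles over shifted spectra, profile classification and salience
    Q, modulation-transfer-function (MTF) classification, vector strength
    and period histograms, rate-independent spike-train distances, neural
    d-prime discrimination thresholds, Gaussian and difference-of-Gaussians
    spectral receptive-field fits, and phenomenological IC models (energy,
    same-frequency inhibition-excitation, and broadband
    modulation-sensitive inhibition).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    signal,
    stats,
    utils,
    withr
Suggests:
    arrow,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
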