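Package: sctnsim
Title: Spiking Continuous-Time Neuron Networks for Sound Processing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulator for the SCTN digital spiking neuron (a leaky
    integrate-and-fire variant with a scheduled shift-subtract leak and
    binary, identity and stochastic-sigmoid activation modes), spike-timing
    dependent plasticity in both its analytic pair-based form and a
    hardware-style event-matrix/B-register form, and the 17-neuron SCTN
    resonator used as a spiking band-pass filter. Provides a complete
    sound-processing chain on top of these blocks: sigma-delta pulse
    density modulation (PDM) encoding of audio, resonator-bank feature
    extraction (SN-MFCC), a one-layer STDP-trained spiking classifier, a
    synthetic sound-event generator for end-to-end evaluation, and a small
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
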