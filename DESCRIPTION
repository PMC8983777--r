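Package: pursuitgain
Title: Gain Noise and Population Decoding in Smooth-Pursuit Initiation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing the trial-to-trial variability of smooth
    pursuit eye movements during their open-loop initiation. Implements a
    generative "gain-noise" model in which sensory, motor and visuomotor-gain
    noise combine multiplicatively, the signal-dependent-noise (Weber
    fraction) variance models used to test it, a split-half bootstrap
    model-comparison procedure, the latency-alignment and time-averaging
    preprocessing applied to eye-speed traces, and a biomimetic simulator of
    a correlated MT (middle temporal area) population read out by parallel
    speed-estimation and gain-control pathways.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0), yaml, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
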