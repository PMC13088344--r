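Package: thermopulse
Title: Motion-Artifact Removal and Multimodal Vitals Estimation for
    Thermal-Film Wearable Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal-processing stack for headband-style thermal-film
    biosensors that record a hot-film channel (pulse pressure waveform plus
    skin thermal conductivity), a cold-film channel (skin temperature), and
    3-axis head acceleration at 100 Hz. Models motion artifact in the pulse
    channel as a second-order spring-damper response to the gravity-subtracted
    acceleration magnitude, recognizes the model parameters (gain, damping
    ratio, natural frequency) per wearer by Bayesian optimization of
    inter-beat pulse-waveform similarity with a Gaussian-process surrogate and
    Expected Improvement, and subtracts the reconstructed artifact to recover
    clean pulse waveforms. Extracts heart rate by windowed FFT with quadratic
    peak interpolation, converts the cold-film voltage to forehead temperature
    through a linear calibration, and estimates total metabolic rate from
    short-time Fourier transform spectrograms of the three channels with a
    compact convolutional network trained by Adam. Ships a synthetic
    multimodal-sensor simulator with full ground truth so the entire pipeline
    is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    tools,
    lhs
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
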