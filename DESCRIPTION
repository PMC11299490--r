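Package: perceptkit
Title: Analysis of Percept-Style Deep Brain Stimulation LFP Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling, simulating, parsing, and analysing
    BrainSense-style local field potential (LFP) recordings from
    sensing-enabled deep brain stimulation (DBS) implants. Includes a
    forward model of the acquisition chain (ADC arithmetic, analog and
    digital filter cascade, 1/f noise, Nyquist folding of stimulation
    artifacts), Welch and Morlet wavelet spectral estimation with
    baseline model fitting, stimulation energy (TEED) and charge-density
    safety arithmetic, circadian and multidien biorhythm detection in
    at-home 10-minute-average band-power trend logs, a reader/writer for
    the vendor-style JSON session-report dialect, and a seeded synthetic
    fixture generator exercising every analysis path.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
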