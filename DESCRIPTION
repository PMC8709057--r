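Package: p300guard
Title: Cybersecure P300 Brain-Computer Interfacing with a Channel-Mixing
    Integrity Scheme
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying and defending against signal-injection
    attacks on P300-based brain-computer interfaces. Provides a synthetic
    multi-channel EEG generator emulating a 14-channel, 128 Hz P300-speller
    recording; the standard P300 preprocessing and feature-extraction chain
    (windowing, zero-phase Butterworth low-pass, detrending, average-based
    decimation, z-scoring); forgery generators for noise-based and
    modulated-noise/median-filter fake-trial attacks; five-kernel support
    vector machine classifiers with a confusion-matrix metric suite and an
    attack-impact measure; the Brain Hacking Recognizer (BHR), a
    pseudo-random channel-mixing integrity scheme that detects injected
    trials by algebraic reconstruction; and a vectorized Monte Carlo
    campaign quantifying the BHR attack-rejection rate.
License: MIT + file LICENSE
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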