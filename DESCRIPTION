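Package: speechstate
Title: Speech-State Detection from Sparse Intracranial Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting overt-speech state (rest
    versus speech) from sparse stereo-EEG-like multichannel recordings.
    Provides a seeded synthetic-data generator emulating a sentence-reading
    paradigm with state-dependent low-frequency and high-gamma (75-150 Hz)
    power modulation; signal preprocessing (anti-alias low-pass or
    high-gamma band-pass, powerline notch bank, z-scoring, decimation);
    speech-responsive channel selection via Welch spectra and paired t-tests
    with Benjamini-Hochberg correction; a compact 1-D convolutional network
    classifier trained with Adam and cosine learning-rate decay; causal
    sliding-window continuous decoding; channel-dropout and region-exclusion
    robustness ablations; and gradient-saliency attribution of per-channel
    and per-region contributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
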