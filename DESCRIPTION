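Package: gaitbci
Title: Gait-Intention Detection from EEG with FFT, Hilbert-Huang and
    Stockwell Band Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An offline and pseudo-online brain-machine-interface pipeline
    for detecting the intention to start or stop walking from multichannel
    EEG. Trials are spatially filtered with a surface Laplacian over the
    full montage, sliced into overlapping 1-s epochs, and summarised per
    electrode as alpha (8-13 Hz), beta (13-32 Hz) and gamma (32-50 Hz) band
    features by one of three interchangeable time-frequency methods: FFT
    band power, Hilbert-Huang marginal-spectrum peaks (empirical mode
    decomposition plus analytic-signal spectra), or Stockwell-transform
    marginal-spectrum peaks. Epochs are classified with an RBF-kernel
    support vector machine and scored with event-detection indices (TPR,
    Acc, FP/min, FPR) and the composite Weighted Discriminator. A synthetic
    EEG generator with 1/f background and event-locked band-power
    desynchronisation makes every stage testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    signal,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
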