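Package: painflex
Title: Pain-State Classification of Stiff Knee Joints from Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pseudo-online detection of the pain state of post-fracture stiff
    knee joints during robot-assisted mobility training, from four-channel
    surface electromyography. Implements zero-phase band-pass/notch
    preprocessing, sliding-window extraction of time-domain, spectral,
    wavelet-packet and sample-entropy features, cost-sensitive linear
    support vector machines and random forests tuned by a double
    cross-validation with a weighted T-value criterion, majority-vote
    decision smoothing, and estimation of the maximum angle position
    (maxAP) from the first detected painless-to-pain transition. A seeded
    synthetic generator of pain-modulated EMG and joint-angle trials makes
    the full pipeline testable without patient recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    ranger,
    signal,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
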