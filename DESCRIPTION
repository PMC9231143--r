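Package: mmgforce
Title: Muscle Force Estimation from Mechanomyography Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates isometric knee-extension force from multichannel
    mechanomyography (MMG) recordings. Provides a seeded synthetic MMG and
    force-trace generator, Butterworth filtering and sliding-window
    segmentation, a 75-dimensional feature bank (time, frequency,
    wavelet-packet and nonlinear-dynamics features), gray relational
    analysis for feature selection, cuckoo search with Levy flights plus an
    improved variant with Tent-chaotic initialization and adaptive control
    parameters, and an epsilon-SVR force model whose penalty and kernel
    width are tuned by the improved cuckoo search.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    signal,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
LinkingTo: Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
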