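Package: ssam
Title: Steady-State Activation Map Networks for EEG Brain-State Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Decodes passive music listening versus active music
    recall/creation brain states from 32-channel EEG. Implements the full
    pipeline: a synthetic EEG generator with planted band- and
    electrode-specific class effects, Butterworth band decomposition into
    the theta/alpha/beta/gamma bands, windowed differential-entropy
    features mapped onto a 9x9 scalp grid, the steady-state activation
    map (SSAM) attention network (per-frame spatial self-attention,
    frame-importance attention, per-band CNN spatial encoding, efficient
    channel attention fusion, softmax classification), subject-dependent
    training with a staged learning-rate schedule and stratified ten-fold
    cross-validation, and post-hoc analyses: attention topomaps, band
    contribution shares, SSAM-time correlation, inter-electrode
    connectivity, and per-electrode permutation significance screening.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
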