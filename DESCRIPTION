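Package: pcgseg
Title: Heart-Sound Segmentation of Phonocardiograms with Recurrent Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-sample segmentation of phonocardiogram (PCG) recordings into
    the four cardiac phases S1, systole, S2 and diastole. Implements the full
    pipeline: Butterworth band-pass filtering, amplitude normalization,
    empirical mode decomposition by sifting, Hilbert analytic-signal envelope
    extraction, and gated recurrent sequence labelers (GRU, bidirectional GRU,
    bidirectional LSTM) trained with Adam on fixed-duration envelope windows.
    Includes WAV and region-table I/O, a labeled synthetic PCG generator so
    every stage runs without external corpora, a per-class evaluation panel
    (accuracy, sensitivity, specificity, precision, F1), and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
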