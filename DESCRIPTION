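Package: standbci
Title: Motor-Imagery EEG Decoding for Sit-to-Stand Brain-Computer Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete decoding stack for binary motor-imagery
    brain-computer interfaces targeting sit-to-stand and stand-to-sit
    intention detection from 17-channel scalp EEG. Provides a synthetic
    session generator with controllable event-related desynchronization
    and injectable artifacts, EDF-based session input/output, epoching
    with peak-to-peak/variance/noise-ratio artifact rejection,
    filter-bank common spatial pattern (FBCSP) feature extraction,
    Ledoit-Wolf regularized linear discriminant analysis, five-fold
    cross-validated and permutation-tested offline evaluation, a
    streaming detection engine with consecutive-label voting and
    information transfer rate metrics, and Morlet-wavelet event-related
    spectral perturbation (ERSP) maps with bootstrap significance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
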