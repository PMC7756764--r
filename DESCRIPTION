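Package: vocalmeter
Title: Automated Measurement of Vocal Stereotypy Duration from Session Audio
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the duration of vocal stereotypy in session audio
    recordings. Each second of audio is summarised by 260 log mel-filterbank
    features (10 frames of 26 coefficients) and classified by a compact
    single-hidden-layer neural network trained with class-weighted
    cross-entropy, dropout, and kappa-based early stopping. Per-second
    predictions are aggregated into session-level engagement percentages and
    validated with between-participant, within-participant, and hybrid
    cross-validation protocols using accuracy, Cohen's kappa, and
    session-by-session correlation. A seeded synthetic-session generator
    produces labelled audio corpora (harmonic vocal events over pink noise,
    with or without overlaid music) so the full pipeline is testable without
    any recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    optparse,
    purrr,
    rlang,
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    e1071,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
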