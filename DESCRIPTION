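Package: eegpls
Title: Group and Single-Participant PLS Analysis of EEG Connectivity and
    Complexity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying longitudinal change in resting-state EEG
    functional connectivity (weighted phase lag index, WPLI) and signal
    complexity (multiscale entropy, MSE), and for asking how well
    group-level patterns of change generalize to individual participants.
    Implements across-epoch Fourier/multitaper and within-epoch Morlet
    WPLI estimators, multiscale sample entropy, age-confound regression,
    mean-centered task PLS-SVD with permutation tests and bootstrap
    stability ratios, non-rotated (contrast-driven) PLS for
    single-participant inference, and group-to-individual pattern
    similarity summaries. Includes a synthetic resting-state EEG cohort
    generator with injectable connectivity and complexity effects so the
    whole pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
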