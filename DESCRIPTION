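Package: memtrace
Title: Synthetic fMRI Pipeline for Time-Dependent Memory Consolidation Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates complete recognition-memory fMRI cohorts (event tables,
    BOLD time series with AR(1) noise and low-frequency drift, multivoxel item
    patterns with controlled encoding-retrieval correlation, and
    signal-detection recognition responses) and analyses them end to end:
    first-level general linear models with a canonical double-gamma
    haemodynamic response, discrete-cosine high-pass filtering and AR(1)
    prewhitening; trialwise t-statistic activation patterns; searchlight
    encoding-retrieval similarity (EOS/ENS); psychophysiological-interaction
    connectivity from seed eigenvariates; signal-detection metrics (d-prime,
    criterion, confidence weighting); and two-by-two between-subjects group
    inference with max-statistic permutation familywise-error control inside
    regions of interest. Designed for desk-scale methodological work on
    pharmacological modulation of systems consolidation, where planted effects
    in the simulator make every analysis stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    RNifti,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
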