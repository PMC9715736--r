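Package: microstatr
Title: Resting-State EEG Microstate Analysis with Synthetic Ground Truth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Microstate analysis of multichannel resting-state EEG:
    global field power (GFP) computation, extraction of topographic maps at
    GFP peaks, polarity-invariant modified k-means clustering with GEV, CV,
    dispersion and Krzanowski-Lai diagnostics, winner-take-all back-fitting
    with temporal smoothing, and per-class microstate features (duration,
    occurrence, coverage, mean GFP, transition probabilities). Includes a
    semi-Markov synthetic EEG generator with known microstate ground truth,
    a two-group cohort simulator with planted clinical-scale couplings, and
    the statistics layer used to compare groups and relate features to
    clinical scores (Welch t-tests, Pearson and age-controlled partial
    correlations, two-factor ANOVA, linear regression).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    signal,
    car,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
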