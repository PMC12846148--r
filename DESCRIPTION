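Package: swbeeg
Title: Short-Term Subjective Well-Being Analytics for Multichannel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline linking short-term subjective well-being (SWB)
    reports to 14-channel EEG recordings. Computes band-resolved relative
    power and frontal alpha asymmetry in pre-report windows, classifies SWB
    with leave-one-out 1-nearest-neighbour models (feature vectors or
    band-filtered time series, Euclidean or dynamic time warping distances),
    fits SMOTE-balanced per-participant linear regressions with
    Benjamini-Hochberg false discovery rate control, derives a
    cross-participant model-transfer distance, and assesses clustering
    consistency through Isomap embedding, k-means partitions, silhouette
    scores and the adjusted Rand index. Includes a synthetic cohort generator
    whose band amplitudes are coupled to a latent comfort process, for
    validating every stage against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    igraph,
    purrr,
    rlang,
    readr,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
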