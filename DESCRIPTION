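Package: soundgate
Title: Categorization of Extremely Brief Auditory Stimuli
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for studying how little auditory information is
    needed to tell voices, music and environmental sounds apart. Generates
    category-structured synthetic source recordings, cuts randomly placed
    gated excerpts (20-200 ms) under peak or RMS amplitude normalization,
    computes cochlear excitation patterns with an ERB-spaced gammatone
    filterbank, summarizes the stimulus set with a global principal component
    analysis (correlation circle, category barycenters and dispersions,
    within- and between-category Euclidean distances), scores forced-choice
    response logs with a hit/false-alarm accuracy index, simulates listeners
    with a distance-based softmax choice model, and links acoustic distances
    to categorization accuracy with standardized multiple regression.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
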