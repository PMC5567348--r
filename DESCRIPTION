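Package: meaburst
Title: Network Burst Propagation Patterns in Multi-Electrode Array Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection and comparison of spontaneous and electrically evoked
    network bursts in multi-electrode array (MEA) recordings of cultured
    neuronal networks. Provides logISI-based single-channel burst detection,
    network-burst assembly with activation rank orders and burst-leader
    statistics, post-stimulus time histogram (PSTH) analysis with adaptive
    separation of early and late response components, shuffle-normalized
    Levenshtein distances between activation patterns, template-matching
    clustering of propagation patterns, and evaluation metrics comparing
    spontaneous with evoked patterns. Includes a synthetic spike-train
    generator with planted propagation templates and ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
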