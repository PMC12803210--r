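Package: syncburst
Title: Calcium-Imaging Trace Analysis and Synchronized Network-Burst Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for fluorescence calcium-imaging traces from
    neuronal populations: sliding-minimum baseline estimation and dF/F0
    normalization, calcium event detection by thresholded local maxima,
    population-level synchronized-burst detection by a fraction-of-active-cells
    threshold, and paired neuron-matched statistics across recording
    conditions. Includes a seeded generator of synthetic bursting-network
    recordings (spike rasters rendered through an indicator kernel with noise
    and drift) so every stage can be validated by parameter recovery.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
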