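Package: hubvuln
Title: Hub Vulnerability Analysis of Wavelet Functional Connectivity Networks
Version: 0.1.0
Authors@R:
    person("Imaging", "Transcriptomics Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline linking regional gene expression from donor
    microarray data to functional-connectivity hubs and their proportional
    loss in neurodegenerative disease groups. Builds random Voronoi
    parcellations of a gray-matter mask, computes scale-2 MODWT wavelet
    correlation networks from BOLD time series, applies framewise-displacement
    motion quality control, maps donor expression samples to imaging regions
    under an interhemispheric symmetry assumption, and runs the permutation
    statistics (hub definition, proportional connectivity loss, expression
    correlations, fluency covariance). Includes a synthetic-data generator
    that emulates the statistical structure of the source data with a
    ground-truth record for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
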