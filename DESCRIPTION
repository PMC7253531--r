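Package: caltrace
Title: Spike Inference and Firing-Phenotype Clustering for Neuronal
    Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for single-channel fluorescence calcium
    imaging of cultured neurons: soma detection and ROI trace extraction
    from movies, moving-average smoothing, block-spline drift correction
    and dF/F0 normalization, supervised (boosted-stump) screening of
    active versus inactive cells, spike inference by the peeling
    algorithm with a single-exponential transient template, per-neuron
    firing and bursting feature extraction, and segregation of firing
    phenotypes by principal component analysis and k-means clustering.
    Includes a synthetic-data generator that emulates recordings of
    bursting neuronal populations so that every stage is testable
    without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
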