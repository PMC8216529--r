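Package: musclenet
Title: Functional Muscle Networks and Classification of Neck-Pain EMG During Gait
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for discriminating chronic neck pain from control
    subjects using surface electromyography (EMG) recorded from neck muscles
    during rectilinear and curvilinear gait. Provides a synthetic multichannel
    EMG cohort generator with analytically known intermuscular coherence,
    zero-phase Butterworth/notch preprocessing with amplitude normalization,
    spectrotemporal EMG feature extraction, Welch magnitude-squared coherence
    (MSC) with band aggregation, band-wise functional muscle networks with
    proportional thresholding and graph-topology metrics (strength,
    betweenness centrality), neighbourhood component analysis (NCA) feature
    weighting, cross-validated K-NN/LDA/SVM classification, and the group
    statistics used throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    MASS,
    e1071,
    igraph,
    nortest,
    jsonlite,
    yaml,
    data.table,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
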