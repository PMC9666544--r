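Package: seizevision
Title: 3D-Video Preprocessing and Action-Recognition Classification of Epileptic Seizures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying epileptic seizure types (frontal-lobe,
    temporal-lobe, non-epileptic) from bedside 3D video: depth-stream
    denoising by grayscale dilation, semi-specialized depth-band cropping
    from fitted scene polynomials, detector-driven bounding-box cropping,
    temporal slicing into 2-second clip samples, masked 7x1024 feature
    sequences, LSTM-FC and average-pooling classifier heads with weighted
    losses and early stopping, and subject-grouped 5-fold cross-validation
    with macro-averaged metrics. Includes a synthetic epilepsy-monitoring-unit
    scene generator (depth + infrared stacks with ground truth) so the whole
    pipeline can be exercised and validated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    nnet,
    png,
    optparse,
    knitr
Config/testthat/edition: 3
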