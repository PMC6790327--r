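Package: wgfc
Title: Static and Dynamic White Matter-Gray Matter Functional Connectivity
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs static and sliding-window dynamic functional
    connectivity within gray matter and between white matter and gray
    matter from resting-state BOLD fMRI time series, summarises dynamic
    connectivity per edge by the root-mean-square of windowed Pearson
    correlations, selects discriminative edges by Fisher-z two-sample
    t-tests, and benchmarks feature subsets with a linear support vector
    machine under leave-one-out cross-validation, reporting accuracy,
    sensitivity, specificity, AUC and F-score. Includes ROI time-series
    extraction from labelled NIfTI volumes, a 0.01-0.1 Hz zero-phase
    bandpass, a regime-switching multivariate Gaussian cohort simulator
    for two-group designs, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    e1071,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
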