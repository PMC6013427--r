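Package: thetaSME
Title: Lateralized Theta Subsequent-Memory Analysis for Intracranial EEG
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for analysing hippocampal
    subsequent-memory and navigation effects in intracranial EEG recorded
    during a virtual spatial-memory (treasure hunt) task. Provides a
    synthetic-cohort simulator with planted, lateralized 1-3 Hz oscillatory
    effects; percentile-rank behavioral accuracy scoring and median-split
    memory labeling; bipolar referencing, band-stop filtering, epoching and
    kurtosis-based artifact rejection; Morlet wavelet time-frequency power
    with log/z transforms and band averaging; cluster-based and sign-flip
    permutation statistics, hemisphere-by-condition lateralization ANOVA and
    1/f-residual narrowband-oscillation detection; and cross-validated
    L2-logistic-regression decoding of memory success from spectral features.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    MASS,
    glmnet,
    pROC,
    car,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
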