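Package: fibwave
Title: Fibrillatory-Wave Complexity Analysis of the Surface ECG in
    Atrial Fibrillation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Extracts atrial fibrillatory (f-wave) activity from multi-lead
    surface ECG recordings of atrial fibrillation by event-synchronous
    adaptive QRST cancellation, quantifies its complexity per lead (f-wave
    amplitude, dominant frequency, organization index, spectral entropy,
    sample entropy), and relates the metrics to ablation outcomes through a
    univariate screen, multivariate logistic regression, ROC cutoff
    selection and a combined dichotomized predictor. Seeded generators for
    synthetic AF ECGs with known ground truth and for synthetic outcome
    cohorts allow the whole pipeline to be validated end to end without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    pROC,
    nortest,
    withr,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
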