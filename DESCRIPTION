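Package: drpbench
Title: Cross-Dataset Generalization Benchmarking for Drug Response Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A benchmarking toolkit for evaluating how well drug response
    prediction models generalize across drug screening datasets. Provides
    three-parameter Hill-slope dose-response curve fitting with goodness-of-fit
    filtering and normalized AUC computation, benchmark-bundle construction
    with reproducible train/validation/test splits, molecular featurization
    (circular fingerprints and 2D descriptors), a standardized
    preprocess/train/infer pipeline contract with baseline regressors, a
    source-by-target cross-dataset evaluation workflow, and the G/Ga/Gn/Gna
    generalization metric family with coverage and statistical-comparison
    analyses. Includes a synthetic multi-study data generator with known
    ground truth so the full workflow is exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    minpack.lm,
    glmnet,
    xgboost,
    nnet,
    ChemmineOB,
    pheatmap,
    parallel
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
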