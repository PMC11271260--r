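Package: fusebench
Title: Benchmarking Dimensionality Reduction and Data Fusion for
    Multimodal Diagnosis Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing dimensionality-reduction methods
    (principal component analysis, denoising autoencoder, LASSO feature
    selection, and a supervised encoder with a bottleneck code layer)
    combined with simple, early, and intermediate data-fusion topologies
    on multimodal tabular cohorts.  Includes a synthetic multimodal
    cohort generator with known latent structure and a Bayes-optimal
    reference classifier, preprocessing filters for visit-level clinical
    tables (feature missingness, baseline-visit selection, scan-visit
    merge windows, age filters), a repeated random-split evaluation
    protocol with normal-approximation confidence intervals, majority
    voting ensembles, model ranking, and permutation feature importance
    attributed to raw per-modality features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
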