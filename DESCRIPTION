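Package: gasvr
Title: Genetic Algorithm Optimization of Support Vector Regression and
    Feature Subsets for QSAR Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wrapper feature selection and hyperparameter tuning for
    RBF-kernel support vector regression with a real-coded genetic
    algorithm. A mixed chromosome carries the three SVR hyperparameters
    (cost C, kernel width gamma, insensitive-zone half-width epsilon)
    together with a fixed-size subset of feature indices; fitness is the
    mean squared error of 10-fold cross-validation, so parameters and
    features are optimized simultaneously rather than in separate passes.
    Includes the surrounding QSAR pipeline: descriptor-table cleaning
    (missing, invariant and near-duplicate columns), Kennard-Stone
    representative train/test splitting, an exhaustive grid-search
    baseline, replicated runs with feature-occurrence analysis, and a
    synthetic descriptor-table generator with known ground truth for
    benchmarking. Motivated by blood-brain-barrier log BB prediction but
    applicable to any continuous-response descriptor table.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    kernlab,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
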