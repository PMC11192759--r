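Package: cellavatar
Title: Signaling-Network Cell Avatars for Drug Response and Combination Synergy Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds in silico avatars of cancer cell lines by conditioning a
    signed, weighted signaling network with expression fold-changes and
    mutation-derived activity caps, then simulates noisy discrete-time
    continuous-valued dynamics to attractors to predict cell fate. Supports
    dose-response screening with four-parameter logistic IC50 fitting, 16x16
    combination grids scored by negative-clamped Bliss independence excess,
    quality control of dose-response monotonicity, K-means discretization of
    synergy scores, systematic single-node perturbation screens for synergy
    and viability biomarkers with Wilcoxon rank-sum significance testing, and
    benchmarking of synergy and monotherapy predictions against reference data
    and standard machine-learning baselines. A synthetic-fixture generator
    provides self-contained networks, omics tables and drug panels with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    minpack.lm,
    nnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
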