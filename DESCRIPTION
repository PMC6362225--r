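Package: connstage
Title: Staged Analysis of Structural Brain Connectomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for cross-sectional analysis of weighted structural brain
    connectomes across ordered clinical stages. Provides consistency-based
    edge masking and weighted network measures (nodal and total strength,
    global efficiency, Onnela clustering, tract-average diffusion scalars),
    covariate-adjusted group statistics with Cohen's d on residuals, an
    exact/asymptotic Jonckheere-Terpstra trend test, a mass-univariate nodal
    trend scan with FDR control for discovering vulnerable subnetworks,
    sparse linear discriminant analysis via penalized optimal scoring with
    leave-one-out evaluation, a synthetic cohort generator with planted
    ground truth for calibration and recovery studies, and an end-to-end
    pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    glmnet,
    jsonlite,
    rlang,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
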