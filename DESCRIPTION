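Package: sfggm
Title: Differential Protein Co-Abundance Networks from Affinity Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for aptamer-based affinity proteomics of
    synovial fluid: limit-of-detection quality control and aptamer filtering,
    batched linear mixed-effect differential abundance with group contrasts,
    joint two-group Gaussian graphical model estimation via node-wise
    group-lasso regression with BIC regularization selection and stability
    selection, differential-network characterization (shared and unique
    edges, degree and betweenness centralities, consensus Louvain
    communities), and cross-platform validation against mass-spectrometry
    protein quantification. Includes a synthetic-data generator with known
    network and effect ground truth for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    pbkrtest,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
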