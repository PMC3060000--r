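Package: qhtsqsar
Title: Hybrid Chemical-Biological QSAR Models of Acute Toxicity from qHTS
    Concentration-Response Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning noisy quantitative high-throughput screening
    (qHTS) cell-viability concentration-response profiles into biological
    descriptors of chemicals and combining them with conventional chemical
    descriptors to build classification models of in vivo acute toxicity
    (rat LD50 categories). Implements a monotonicity-enforcing noise filter
    controlled by a baseline threshold (THR) and a maximum curve deviation
    (MXDV), binary curve fingerprints, descriptor curation and range scaling,
    class balancing by structural down-sampling, sphere-exclusion
    training/test splitting, k-nearest-neighbour ensembles with simulated
    annealing descriptor selection and applicability domains, random forest
    companions, consensus scoring with dual classification thresholds,
    five-fold external validation, y-randomization robustness testing, and a
    synthetic data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    minpack.lm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
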