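Package: screenmf
Title: Matrix Factorization for Sparse Cancer Screening Histories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs complete latent risk profiles from sparse,
    irregular cervical cancer screening histories using regularized
    low-rank matrix factorization with temporal smoothness penalties,
    optional inverse-propensity discrepancy weights, and per-subject
    time-shift alignment. Provides a discrete latent-state observation
    model for predicting an individual's next screening result, a
    synthetic-data generator emulating registry-like scarcity and class
    imbalance, and model evaluation via Kaplan-Meier estimates compared
    through the probability of agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
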