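Package: mgpattn
Title: Multitask Gaussian Process Attention Networks for Early Sepsis Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end early sepsis prediction from irregularly sampled intensive-care
    time series. A multitask Gaussian process with Ornstein-Uhlenbeck time kernels and
    free-form feature covariances imputes vitals and laboratory values onto a regular
    hourly grid; Monte Carlo samples from the posterior feed an interpretable classifier
    built from causal temporal convolutions with attention over time and over features,
    trained jointly with the Gaussian process by gradient descent. Includes Sepsis-3
    labelling from antibiotic, blood-culture and SOFA event tables (with a
    missing-contributor-as-healthy policy), a cohort construction pipeline
    (case-control matching, horizon augmentation, splitting, normalization), the
    InSight window-statistics baseline with triplet correlations and adjusted-quantile
    trichotomization, ridge logistic regression baselines, and a synthetic cohort
    generator so the whole pipeline is exercisable without access to restricted
    clinical databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    yaml,
    jsonlite,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
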