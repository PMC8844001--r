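Package: dfcstates
Title: Dynamic Functional Connectivity States from Temporal-Derivative Coupling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects recurring whole-brain connectivity states in resting-state
    fMRI ROI time series using the multiplication of temporal derivatives (MTD)
    coupling estimator with sliding-window smoothing, k-means clustering under
    cityblock (Manhattan) distance, and fractional-occupancy change scores
    across repeated runs. Includes motion quality control (framewise
    displacement and DVARS marking with interpolation), salivary cortisol
    area-under-the-curve summaries (trapezoidal, with-respect-to-ground and
    increase), trait-mindfulness questionnaire scoring, a pre-planned
    inferential battery (paired t-tests, Pearson and Spearman correlations,
    family-wise p-value adjustment), and a synthetic-cohort generator with
    covariance-switching BOLD so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    Matrix
Config/testthat/edition: 3
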