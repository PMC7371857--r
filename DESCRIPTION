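Package: paldyn
Title: Pathway Activity Dynamics of Corticosteroid Response from Time-Series Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes time-series gene expression data into pathway activity
    levels (PALs) by singular value decomposition, assesses their statistical
    significance by fractional-coverage Fisher tests and bootstrap resampling,
    clusters bootstrapped PAL ensembles with k-means and the gap statistic, and
    explains PAL dynamics with mechanistic pharmacokinetic / glucocorticoid
    receptor / indirect-response ODE models of methylprednisolone action under
    acute (bolus) and chronic (infusion) dosing, including automated
    classification of transient, persistent, rebound, tolerance and
    new-steady-state behaviours. Includes a synthetic-data generator emulating
    the acute (17 timepoints, 0-72 h) and chronic (11 timepoints, 0-170 h) rat
    study designs so the whole analysis is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
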