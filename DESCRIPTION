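Package: lesionconn
Title: Functional Connectivity and Connectomic Consequences of Focal Brain Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying connectional and connectomic diaschisis in
    resting-state fMRI: a confound-aware connectivity estimator based on a
    general linear model with restricted-maximum-likelihood (ReML) estimation
    of temporal autocorrelation over a family of exponential covariance
    components, yielding degrees-of-freedom-corrected Z connectivity;
    network-level block statistics and segregation; percentile-thresholded
    graph metrics (global clustering, global efficiency, small-worldness,
    isolates); single-case and group statistics (pooled-variance single-case
    t, Stouffer combination, rank-sum); and a seeded synthetic cohort
    generator that plants lesion effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    withr
Config/testthat/edition: 3
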