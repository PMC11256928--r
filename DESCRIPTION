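Package: xldfa
Title: Decoy-Free False Discovery Rate Estimation for Cross-Linking
    Mass Spectrometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the false discovery rate (FDR) of cross-linked
    peptide-spectrum matches (XL-MS/MS) without decoy databases. Models the
    scores of the top- and second-ranked candidate peptide pairs per spectrum
    as a pair of skew-normal mixtures with shared correct, partially
    incorrect, and incorrect components, fitted by a constrained
    expectation-conditional-maximization algorithm: closed-form
    skew-normal parameter updates via the truncated-normal stochastic
    representation, mixing-weight updates under latent-structure inequality
    constraints solved through Karush-Kuhn-Tucker systems with a greedy
    active set, and pairwise density-dominance constraints enforced by
    binary-search repair. Includes a model-based FDR estimator built on the
    skew-normal survival function (Owen's T), the target-decoy baseline,
    labelled synthetic-data generators for calibration studies, and
    bootstrap assessment of FDR-threshold variability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
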