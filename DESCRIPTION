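Package: limbrsa
Title: Representational Similarity Analysis of Sensorimotor Digit Maps with Simulated fMRI Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates block-design fMRI activity patterns for digit movements
    with known representational geometry, estimates cross-validated Mahalanobis
    (crossnobis) representational dissimilarity matrices with multivariate
    noise normalization, and computes typicality, split-half reliability,
    two-dimensional projections (classical MDS with Procrustes alignment),
    and an inferential layer including forward stepwise regression with
    bootstrap replicability and a group-difference-calibrated Bayes factor.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
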