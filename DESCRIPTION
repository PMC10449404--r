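Package: metaI
Title: Information-Theoretic Measures of Metacognitive Sensitivity and
    Efficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes the mutual information between the accuracy of
    binary decisions and the confidence reported about them (meta-I),
    together with two normalized efficiency ratios (meta-I1r, meta-I2r),
    confidence-bin threshold optimization, permutation-based correction of
    finite-sample estimation bias, and a reference meta-d'/M-ratio fitter
    under the equal-variance Gaussian type-2 signal-detection model.  Also
    provides an exactly solvable second-order observer, in which a
    confidence rater receives a noisy read-out of the decision-maker's
    evidence plus an independent signal about the stimulus, with expected
    measures by numerical quadrature and a seeded trial simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
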