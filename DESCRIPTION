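Package: sgadt
Title: Adaptive SVR Imputation with Genetic Kernel Search and Decision-Tree Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Missingness-regime-driven imputation of non-class attributes in
    tabular datasets using epsilon-insensitive support vector regression whose
    kernel and hyperparameters are tuned by a genetic algorithm, with iterative
    refinement at moderate missingness and k-nearest-neighbour bootstrapping at
    high missingness, followed by interpretable CART classification with
    cost-complexity pruning. Includes MAR missingness injection with calibrated
    rates, latent-factor synthetic data generators with known ground truth,
    seven baseline imputers, and a cross-validated benchmarking and
    missingness-sweep harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    nnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
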