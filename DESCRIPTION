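Package: berrycount
Title: Semi-Supervised Density-Map Counting of Clustered Fruit from Point Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Counts densely clustered objects (grape berries) in field images
    from point annotations. Point labels are blurred into unit-integral Gaussian
    density maps whose sum equals the object count; a dilated-convolution network
    regresses the density map and, alongside it, k binary density-level
    segmentation predictors absorb supervision from unlabeled images through
    mutual-exclusion-corrected pseudo-labels. A cosine density-difference loss
    amplifies feature contrast between density levels. Includes a seeded
    synthetic berry-scene generator, a semi-supervised training loop, counting
    metrics (MAE, RMSE, R squared), comparison-table arithmetic, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
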