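Package: methylmiss
Title: Benchmarking Missing-Value Imputation for DNA Methylation Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to benchmark missing-value imputation on DNA methylation
    matrices under the beta-value and M-value representations. Provides a
    synthetic cohort generator reproducing the bimodal, heteroscedastic and
    correlated structure of Illumina array beta-values; simulators for the
    MCAR, MAR and MNAR (low/mid/high range) missing-data mechanisms; seven
    imputation algorithms (column mean, k-nearest-neighbour, iterative
    truncated SVD, soft-thresholded SVD, regularised iterative PCA, chained
    regression with a pluggable learner, and a pseudoinverse multi-output
    linear model exploiting inter-sample correlation); evaluation on the
    beta scale with MAE, RMSE and per-range error profiles; and a paired
    Wilcoxon signed-rank comparison procedure with Benjamini-Hochberg
    adjustment, intra-method scale winners and a relaxed best-method set.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    optparse,
    ranger,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
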