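Package: gsreg
Title: Regularized Regression Models for Genomic Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Comparative evaluation of six regularized linear regression
    models for genomic prediction of breeding values from dense SNP
    markers: ridge regression, ridge regression BLUP (penalty estimated by
    REML), the lasso, the adaptive lasso, the elastic net and the adaptive
    elastic net. Includes a pedigree-based population simulator with
    linkage-disequilibrium-bearing founders, gene dropping under the
    Haldane map function and configurable quantitative-trait architecture;
    a cyclical coordinate-descent solver with pathwise warm starts and
    adaptive weights; family-stratified cross-validation for tuning; and
    accuracy reporting against true genomic values, true breeding values
    and held-out phenotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
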