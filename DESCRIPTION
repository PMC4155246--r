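Package: tcglm
Title: Two-Step Negative Binomial GLM Analysis of RNA-Seq Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Detects differentially expressed genes in RNA-seq time-course
    experiments by polynomial regression with negative binomial generalized
    linear models. A genome-wide screen tests each gene's full polynomial
    model against the intercept-only model with a deviance chi-square test
    under Benjamini-Hochberg false discovery rate control, then a per-gene
    backward stepwise regression retains only significant coefficients and
    filters the result on deviance-explained R-squared. Includes a negative
    binomial count simulator with a known truth table, TMM normalization and
    low-count filtering helpers, an FDR/FNR benchmarking harness, and a small
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Matrix,
    dplyr,
    edgeR,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
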