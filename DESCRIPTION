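Package: evoselect
Title: Evolutionary and Stepwise Gene-Subset Selection for Two-Class
    Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wrapper feature selection for two-class gene-expression
    matrices. Genes are pre-filtered by the Welch t statistic, then a
    genetic algorithm searches binary gene masks under a fitness that
    combines test misclassification, subset size, and a mutual-information
    redundancy penalty; a stepwise forward selection baseline is included.
    Candidate subsets are scored by any of six classifiers, among them
    C-MANTEC, a constructive neural network of competing thermal
    perceptrons with a majority-gate output and a noise-pattern filter.
    A repeated-holdout harness reports accuracy, false-positive and
    false-negative rates, parameter-sweep compactness, gene-selection
    frequencies, and Friedman comparisons, and a synthetic-data generator
    plants informative and redundant genes so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    class,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
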