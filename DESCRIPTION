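Package: wrapfs
Title: Genetic-Algorithm Wrapper Feature Selection with Information-Theoretic Filters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wrapper feature selection for biomedical classification tasks.
    A single-population genetic algorithm searches binary feature masks under
    a size-penalised fitness function wrapped around in-house naive Bayes and
    k-nearest-neighbour classifiers.  Greedy information-theoretic filters
    (mRMR, JMI, CMIM, ICAP) and a class-correlation baseline provide optional
    pre-selection for a two-phase hybrid pipeline.  Includes nested k-fold
    cross-validation, confusion-matrix performance metrics (sensitivity,
    specificity, GMean, PPV, F1, accuracy, MCC), a chance-corrected
    selection-stability statistic, synthetic benchmark generators with known
    ground truth, and utilities for comparing feature-selection methods.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    parallel
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
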