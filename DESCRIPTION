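Package: rejectr
Title: Post-Hoc Error-Rate Control for Multi-Class Classifiers via
    Per-Class Confidence Thresholds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for selective classification with a reject option.
    Given a table of classifier outputs (ground truth, predicted class,
    top softmax score), rejectr tunes one confidence threshold per class
    on an independent scored dataset under one of three lexicographic
    goals (maximize correct classifications, bound misclassifications
    below 5%, or minimize misclassifications), then reroutes test
    predictions scoring at or below their predicted class's threshold to
    an "unsure" class. Includes per-class rate computation (correct,
    misclassified, unsure, coverage, precision of kept predictions),
    score-quantile diagnostics, a synthetic score-table simulator with a
    closed-form oracle, report rendering, plotting, and a command-line
    interface covering simulate, tune, apply, evaluate, and benchmark
    workflows.
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
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
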