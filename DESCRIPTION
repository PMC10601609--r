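Package: svmga
Title: Embedded Genetic-Algorithm Feature Selection for Support Vector
    Machine Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature selection for small-sample, high-dimensional binary
    classification problems, such as predicting clinical outcomes from
    wavelet-derived physiological features. Implements an embedded wrapper
    method in which a genetic algorithm searches the space of binary
    feature masks and scores each candidate subset by a three-term fitness
    function combining inverse training accuracy, subset cardinality, and
    the inverse geometric margin of a linear support vector machine
    trained on that subset. Also provides the mutual-information filter
    benchmark it is compared against (relevance ranking, threshold
    selection, and sequential-elimination performance sweeps over four
    reference classifiers), a seeded synthetic cohort generator with
    planted informative features for validation, and end-to-end experiment
    orchestration with deterministic artifact output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    rpart,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
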