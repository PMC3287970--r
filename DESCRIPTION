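Package: cpplsElim
Title: Regularized Backward Variable Elimination with Canonical Powered
    Partial Least Squares
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Parsimonious variable selection for two-class discrimination
    problems with many more variables than samples. Fits Canonical Powered
    Partial Least Squares (CPPLS) regression on a dummy-coded response,
    classifies by linear discriminant analysis on the predicted dummy
    values, and greedily eliminates weak variables using one of three
    importance criteria (loading weights, jackknife q-values of the
    regression coefficients, or variable importance on projections).
    Two McNemar-test regularizations keep the model parsimonious: the
    first picks the smallest component count not significantly worse than
    the cross-validated optimum, the second the smallest variable set.
    Includes a nested cross-model-validation evaluation protocol, a
    selectivity-score stability measure with a permutation null, a
    codon/di-codon featurizer turning coding-sequence FASTA files into
    relative-frequency predictors, and a synthetic-data generator with
    known informative variables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
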