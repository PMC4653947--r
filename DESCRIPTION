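Package: dvcscan
Title: Differential Variance and Co-Expression Scoring Along Cell-State Transitions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects genes whose expression variance and co-expression
    relationships change between an ordered series of cellular states, as
    happens when a cell population approaches a critical transition such as
    stem-cell differentiation. Co-expression modules are defined at the
    reference state by average-linkage clustering of correlation distances
    with a hybrid dynamic tree cut; each gene is then scored by the maximal
    log-ratio, across post-reference states, of a composite index combining
    its within-module correlation, replicate variance, and outside-module
    correlation. Companion analyses include Welch t-tests and fold-change
    calls for differential expression, F-tests for differential variance,
    Benjamini-Hochberg adjustment, hypergeometric gene-set enrichment, and
    ortholog-mapped cross-dataset overlap tests. A synthetic-data generator
    with planted transition modules provides ground truth for end-to-end
    verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    limma
Config/testthat/edition: 3
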