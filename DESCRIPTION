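Package: mhscca
Title: Sparse Canonical Correlation Analysis with Multiple Hold-Out Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Doubly-multivariate brain-behavior association analysis for
    multi-site developmental cohorts: rank-weighted principal component
    analysis of functional-connectivity features, sparse canonical
    correlation analysis by penalized matrix decomposition, site-stratified
    multiple hold-out validation with permutation inference and bootstrap
    stability, two cross-study generalizability procedures (gold-standard
    projection and bidirectional qualitative replication), network-module
    interpretation of fitted dimensions, and a synthetic two-view cohort
    generator with planted sparse canonical structure for method
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
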