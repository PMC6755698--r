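Package: hmcdrift
Title: Hierarchical Multi-Label Classification and Annotation Drift Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for hierarchical multi-label classification (HMC) of
    protein function annotations and for auditing annotation drift between
    dataset versions. Implements label hierarchies (FunCat-like trees and
    GO-like directed acyclic graphs) with ancestor closure and deepest-path
    levels, readers and writers for the Clus ARFF HMC dialect, the
    annotation-update procedure (alternate-ID merging, obsolete-term
    removal, hierarchy-subset construction), a random forest of predictive
    clustering trees, pooled (micro-averaged) precision-recall evaluation,
    a synthetic benchmark generator with controlled annotation drift, the
    cross-version change-detection evaluation, and Friedman-Nemenyi method
    comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
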