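Package: m6amtools
Title: Feature Encoding and Boosted-Tree Classification of m6Am Sites in RNA Windows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for predicting N6,2'-O-dimethyladenosine (m6Am) sites
    from fixed-length RNA sequence windows centered on a candidate adenosine.
    Implements nine numeric sequence-encoding schemes (pseudo electron-ion
    interaction potential, hash decimal conversion, dinucleotide binary
    encoding, nucleotide chemical properties, pseudo k-tuple nucleotide
    composition, dinucleotide numerical mapping, k-mer counts, series
    correlation pseudo trinucleotide composition, and k-spaced nucleotide
    pair frequencies), extremely-randomized-trees feature-importance ranking
    with an equidistant prefix search for subset selection, gradient-boosted
    decision-tree training with grid-search tuning, stratified k-fold
    cross-validation with the standard six binary-classification metrics,
    balanced sub-training splits for heavily imbalanced benchmarks, and a
    synthetic window generator with a plantable class signal so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    ranger,
    stats,
    tools,
    utils,
    xgboost
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
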