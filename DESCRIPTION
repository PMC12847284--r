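Package: nsbc
Title: N-Similarity Binary Classification for Clinical Tabular Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An explainable associative classifier for mixed-type, often
    class-imbalanced clinical tables. Features are imputed, label-encoded,
    scaled to nonnegative integers and converted to reflected-binary (Gray)
    code; the concatenated bit strings of the training set form a memory
    matrix, and a query is classified by summing, within each class, the n
    largest Hamming similarities between the query and the stored patterns.
    Includes stratified k-fold cross-validation with balanced accuracy,
    imbalance-ratio reporting, Friedman mean-rank comparison of classifiers
    with Holm step-down post-hoc tests, a synthetic generator for imbalanced
    mixed-type tables, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    foreign,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
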