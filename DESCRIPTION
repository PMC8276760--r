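Package: recspots
Title: Classification of Meiotic Recombination Hot and Cold Spots in Yeast
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for defining and classifying meiotic recombination
    hotspots and coldspots in Saccharomyces cerevisiae from Spo11-oligo
    signal. Calls coldspots as long zero-signal runs, extracts sequence
    compositional features (GC content, GC skew, dinucleotide mutual
    information, Laplace-smoothed k-mer composition), DNA shape and
    physical-property profiles from k-mer lookup tables, and mean
    epigenetic signal features; trains and evaluates five binary
    classifiers (random forest, linear SVM, logistic regression,
    Gaussian naive Bayes, CART) under stratified five-fold
    cross-validation with pooled-decision-value ROC analysis; and
    provides incremental feature selection with ANOVA ranking plus
    recursive correlated-feature pruning. A fully seedable synthetic
    benchmark generator makes every stage testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    randomForest,
    e1071,
    rpart
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
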