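Package: aimpanel
Title: Ancestry-Informative SNP Panel Selection and Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for biogeographic-ancestry classification from exome
    variant calls. Encodes VCF genotypes into a binary samples-by-
    (polymorphism, genotype) presence matrix, ranks variants by per-population
    distinctiveness, searches for a minimal ancestry-informative marker (AIM)
    panel with a genetic algorithm whose fitness is the minimum per-class
    one-vs-all F1-score, and benchmarks support vector machine, random forest
    and gradient-boosted-tree classifiers under stratified cross-validation.
    Includes a synthetic cohort generator (Balding-Nichols allele-frequency
    model with planted informative markers) for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR,
    caret,
    e1071,
    ranger,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
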