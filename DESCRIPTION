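Package: oxyprot
Title: Classification of Oxygen-Binding Proteins from Sequence and
    Evolutionary Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies oxygen-binding proteins (hemoglobin, myoglobin,
    leghemoglobin, erythrocruorin, hemerythrin, hemocyanin) from primary
    sequence using support vector machines. Sequences are encoded as
    amino-acid composition (20-d), dipeptide composition (400-d),
    min-max-normalized PSSM composition (400-d), or a hybrid of the first
    two (420-d). Provides a binary oxygen-binding discriminator plus six
    one-vs-rest sub-class models, repeated stratified five-fold
    cross-validation, threshold-resolved accuracy / sensitivity /
    specificity / Matthews correlation coefficient, ROC analysis, a
    cross-class confusion matrix, a parser for NCBI PSI-BLAST ASCII PSSM
    files, and a seeded synthetic benchmark generator with class-specific
    residue-composition biases for end-to-end testing without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
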