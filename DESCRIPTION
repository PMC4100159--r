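Package: snoANBPB
Title: Prediction of Protein S-Nitrosylation Sites with Adapted
    Normal-Distribution Bi-Profile Bayes Encoding
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Sequence-based prediction of S-nitrosylated cysteines.
    Fixed-length peptide windows centered on candidate cysteines are
    encoded by adapted normal-distribution bi-profile Bayes (ANBPB)
    position-specific posterior probabilities together with two
    physicochemical pseudo-amino-acid composition terms, and classified
    by a class-weighted soft-margin support vector machine with a radial
    basis kernel. Includes window extraction from FASTA with terminal
    "X" padding, position-specific propensity analysis, jackknife and
    repeated stratified k-fold evaluation with Sn/Sp/Acc/MCC reporting,
    confusion-matrix reconstruction from published rates, and a seeded
    synthetic-data generator with planted positional enrichments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    jsonlite,
    e1071,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: SequenceMatching, Classification, Proteomics,
    SupportVectorMachine
RoxygenNote: 7.3.3
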