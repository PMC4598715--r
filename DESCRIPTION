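Package: napminer
Title: Genome-Guided Prediction and LC-MS/MS Detection of Modular Natural Products
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines bacterial DNA or protein sequences for nonribosomal peptide
    synthetase (NRPS) and polyketide synthase (PKS) gene clusters, predicts the
    chemical scaffolds they encode from domain architecture and substrate calls,
    enumerates combinatorial libraries of hypothetical structures (including
    deoxysugar prediction from a glycogenomic code and scaffold glycosylation),
    fragments candidate structures in silico along amide, ester and glycosidic
    channels, and locates matching compounds in LC-MS/MS runs via scored
    fragment matching with decoy normalization and a retention-time bucketed
    discovery chart.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ChemmineR,
    ChemmineOB,
    mzR,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
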