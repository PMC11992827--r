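Package: ctpdn
Title: Weighted Compound-Target-Pathway-Disease Networks and
    Machine-Learning Screens for Herbal Formula Pharmacology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for valuing candidate effective compounds of a
    multi-component (herbal) formula. Builds a weighted
    compound-target-pathway-disease network from docking scores,
    protein-protein interaction scores and pathway membership, ranks
    compounds by Floyd-Warshall shortest paths to disease nodes, trains
    and evaluates a feature-based compound-target interaction classifier
    (AdaBoost over molecular fingerprints, ADMET levels and protein
    physicochemical descriptors), and runs an untargeted serum
    metabolomics screening chain (missingness/QC-RSD/variance filters,
    sum-log10-centre normalisation, PLS-DA VIP and fold-change screening,
    random-forest biomarker panels). A synthetic-data module generates
    all inputs with known ground truth so every stage is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rpart,
    randomForest,
    seqinr,
    ChemmineR,
    stats,
    utils
Suggests:
    ChemmineOB,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
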