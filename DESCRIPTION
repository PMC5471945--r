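Package: metalike
Title: Metabolite-Likeness Screening for Enzyme-Modulator Drug Repositioning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores the structural resemblance of drugs to endogenous enzyme
    substrates (metabolite-likeness) with MACCS substructure fingerprints and
    the Tanimoto coefficient, builds drug-by-metabolite similarity matrices
    and detects their high-similarity clusters, assembles a gold-standard
    positive set of antimetabolite-enzyme-substrate relations, assesses
    per-relation significance against the substrate's similarity distribution
    over all drugs, calibrates a decision threshold by maximizing Youden's J
    on the ROC curve, and enumerates repositioning candidates per enzyme
    above the calibrated threshold. Ships a worked fixture set of
    antimetabolites and their substrates plus a seeded synthetic fingerprint
    generator so the full pipeline runs without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
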