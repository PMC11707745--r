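Package: bcstools
Title: QSPR Modeling and Provisional Biopharmaceutics Classification of Small
    Molecules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Curates structure-property datasets from SMILES input, featurizes
    molecules as circular fingerprints, physicochemical descriptor panels,
    attributed molecular graphs and force-field optimized 3D conformers, and
    trains gradient-boosting regressors for four oral-absorption endpoints
    (aqueous solubility log S, lipophilicity log P and log D, and Caco-2
    apparent permeability log Papp). Predicted properties are converted into a
    provisional Biopharmaceutics Classification System (BCS) class via the
    dose-number solubility rule and metoprolol-anchored permeability cutoffs,
    with confusion-matrix tooling and bundled external-validation tables for
    evaluating the classification rules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    xgboost
Suggests:
    optparse,
    ranger,
    testthat (>= 3.0.0)
SystemRequirements: OpenBabel (obabel on PATH); Python with RDKit (optional,
    for 3D conformer embedding)
Config/testthat/edition: 3
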