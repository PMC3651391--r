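Package: codp
Title: Combination of Different Properties for MSH6 Missense Variant
    Pathogenicity Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the pathogenicity of missense variants in the DNA
    mismatch-repair protein MSH6 by combining three sequence-based component
    scores (a domain-normalized MAPP impact score, SIFT and PolyPhen-2 HumVar)
    with two structure-derived features (relative solvent accessibility and
    the side-chain heavy-atom change) through a logistic regression model
    (the CoDP joint score). Includes a Shrake-Rupley solvent-accessible
    surface area engine for PDB structures, an evidence-based rule engine
    that classifies variant carriers as likely or unlikely Lynch syndrome
    from clinical and molecular data, and the full evaluation protocol
    (confusion metrics, ROC/AUC, Youden cut-off selection, Wilcoxon rank-sum
    comparison and leave-one-out jackknife), together with transcribed
    reference datasets and synthetic-data generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
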