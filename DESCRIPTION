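Package: pharmscreen
Title: Precision-Calibrated Consensus Ranking for Pharmacophore-Based
    Virtual Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Treats ligand-based pharmacophore models as probabilistic
    one-class classifiers. Each model is assigned an activity probability
    equal to its precision on a labelled calibration set, and compounds are
    ranked by consensus of the models they match using the Max or Mean
    combination scheme (with the common-hits approach and OR-consensus as
    baselines). Includes a simplified 3D feature matcher for typed
    pharmacophore feature points, virtual-screening evaluation metrics
    (enrichment factors at fixed fractions, BEDROC with fraction-derived
    alpha, ROC AUC, precision and recall), and a synthetic benchmark
    generator with analytically known model precisions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    ChemmineR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
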