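Package: mtqsar
Title: Multi-Target QSAR Classification with Atom-Based Quadratic Indices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-target quantitative structure-activity relationship
    (mt-QSAR) classification of kinase inhibitors assayed under multiple
    experimental conditions. Computes atom-based quadratic indices
    (non-stochastic and stochastic) over eight atomic properties, converts
    them into condition-deviation descriptors by the Box-Jenkins moving
    average approach, selects linear discriminant models with a genetic
    algorithm, fits random forest classifiers, and provides a full
    validation battery (Wilks' lambda statistics, Y-randomisation,
    applicability domain by the standardisation approach, ROC/AUC,
    cross-validation), Bemis-Murcko ring-fragment contribution scoring and
    multi-condition consensus virtual screening. Includes a synthetic
    condition-annotated molecule generator with a planted
    descriptor-activity relationship so the whole pipeline is testable
    end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    randomForest,
    stats,
    tools,
    utils
Suggests:
    ChemmineR,
    MASS,
    pROC,
    testthat (>= 3.0.0),
    withr
SystemRequirements: OpenBabel (obabel command-line tool)
Config/testthat/edition: 3
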