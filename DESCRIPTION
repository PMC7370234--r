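Package: trailstrat
Title: Predicting Melanoma Responsiveness to TRAIL-Receptor Agonist /
    IAP Antagonist Combination Treatment from Apoptosis Protein Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable implementation of a pattern-recognition
    pipeline that predicts whether melanoma models respond synergistically
    to combined TRAIL-receptor agonist and IAP antagonist treatment from
    pre-treatment expression of 19 apoptosis pathway proteins. Provides
    Webb fractional-product synergy scoring of factorial dose-response
    grids, a standardize/PCA/LDA response classifier with Kaiser-criterion
    component retention, leave-one-out cross-validation with strict
    out-of-training projection of held-out samples, Pearson correlation
    merit feature ranking with iterative predictor reduction, and an
    in silico cohort trial that maps transcriptome profiles onto the
    measured protein scale through per-protein min-max point-to-point
    interpolation. Includes synthetic-data generators that emulate the
    statistical structure of the measured inputs so that every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
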