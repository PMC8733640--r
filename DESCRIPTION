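Package: corneaE
Title: Corneal Elastic Modulus from Air-Puff Deformation Examinations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates Corvis-ST-like air-puff corneal deformation
    examinations with known ground truth, extracts dynamic corneal response
    (DCR) parameters and the air-puff-force versus apex-displacement slope,
    and converts that slope into a corneal elastic modulus through a
    shallow-spherical-shell (Reissner) relation.  Includes the statistical
    battery used to evaluate keratoconus screening indices (normality,
    Bland-Altman/ICC/CCC agreement, one-way ANOVA with LSD contrasts,
    Pearson correlation, ROC analysis with Youden cutoffs and DeLong paired
    AUC comparison) and a small 12-5-1 backpropagation network trained with
    Levenberg-Marquardt updates for three-group classification of healthy,
    forme fruste keratoconus and clinical keratoconus corneas.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    nortest,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
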