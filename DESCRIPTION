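Package: mlcqsar
Title: Micellar Liquid Chromatography Descriptors and QSAR Models for
    Blood-Brain Barrier Permeation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building quantitative structure-activity relationship
    (QSAR) models of blood-brain barrier permeation (log BB) from micellar
    liquid chromatography (MLC) retention data and in-silico molecular
    descriptors. Fits the Foley retention model 1/k = 1/km + (KAM/km)[M] to
    per-compound retention series and derives the slope-based micellar
    lipophilicity descriptor log(km/KAM); quantifies descriptor redundancy by
    correlation-based similarity and hierarchical clustering; enumerates and
    fits multiple linear regression models over descriptor groups; computes a
    full validation battery (R2, adjusted and predicted R2, leave-one-out
    PRESS, Q2, F, VIF) with collinearity screening; and characterizes each
    model's applicability domain by the leverage approach (Williams plot,
    warning leverage h* = 3(p+1)/n). Ships a 65-compound heterocyclic
    drug-like reference dataset and a synthetic-data generator for end-to-end
    pipeline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite,
    optparse,
    knitr
VignetteBuilder: knitr
Config/testthat/edition: 3
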