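Package: sdmensemble
Title: Presence-Background Maximum-Entropy Niche Modelling with Subset
    Screening and Projection Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for species distribution modelling with presence-only
    occurrence data: a penalized maximum-entropy (Gibbs) model with linear,
    quadratic, product, hinge and threshold features; AICc-based tuning over
    regularization multipliers and feature-class sets; spatial-transfer
    screening of climate-variable subsets with AUC, True Skill Statistic and
    omission gates; TSS-optimal binarization; binary-consensus and
    uncertainty mapping; and a multi-GCM, multi-RCP future-projection
    ensemble with per-GCM centered deviation maps. A synthetic-data module
    generates spatially autocorrelated climate rasters, pseudo-GCM future
    scenarios and virtual-species occurrences so the full pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
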