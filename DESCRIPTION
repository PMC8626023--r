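Package: coliboot
Title: Composite Scoring, MPO Quantification and Bootstrap Synergy Testing
    for DSS-Colitis Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable analysis pipeline for preclinical dextran sulfate
    sodium (DSS) colitis drug-combination studies. Computes the composite
    macroscopic colon-damage score (stool consistency, ulcers, colon
    length/weight percent-change bins, fecal blood) and the microscopic
    histology score, converts kinetic plate-reader absorbance traces into
    myeloperoxidase (MPO) activity in milliunits per gram of wet tissue via
    a purified-peroxidase standard curve, and assesses drug synergy between
    monotherapy and combination arms with a bootstrap hypothesis test on
    the absolute difference in group means (pooled-null resampling, 10,000
    iterations by default), backed by an exact small-sample enumeration
    oracle. A synthetic-cohort generator with configurable group effects
    and an optional synergy shift makes the whole pipeline testable without
    animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr,
    optparse
Config/testthat/edition: 3
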