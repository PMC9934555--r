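Package: mavescore
Title: Variant Effect Map Scoring and Clinical Calibration for TileSeq Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Turns pre- and post-selection TileSeq variant read counts from a
    multiplexed assay of variant effect (MAVE) into functional impact scores
    with regularized standard errors, assembles cross-isoform combined maps
    with propagated uncertainty and delta scores, and calibrates scores for
    clinical use: balanced precision-recall evaluation, Gaussian
    log-likelihood-ratios of pathogenicity, and ACMG/AMP evidence-strength
    thresholds derived from posterior-probability constraints. Includes a
    synthetic TileSeq data generator with known ground-truth fitness so the
    whole pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
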