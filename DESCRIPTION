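Package: pillarbeat
Title: Micropillar-Based Quantification of Cardiomyocyte Contractility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tracks elastomeric micropillar (micropost) tops in time-lapse
    microscopy of beating cardiomyocytes, converts sub-pixel deflections to
    contraction force through Euler-Bernoulli cantilever mechanics, and
    analyses beat dynamics, contraction direction and alignment, and
    drug-induced force changes. Includes a synthetic beating-pillar video
    simulator with per-frame ground truth, automatic pillar detection with
    sub-pixel refinement, normalized cross-correlation tracking, beat
    segmentation with directional and axial circular statistics, and
    group-level comparisons (mean, SEM, Student's t-test).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    graphics,
    jsonlite,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
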