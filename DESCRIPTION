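Package: ethonight
Title: Rule-Based Nocturnal Ethogram Coding from Pose-Estimation Keypoints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts animal pose-estimation keypoint trajectories and
    per-frame object-detection streams into ethogram behavior sequences via
    configurable coordinate-zone rules, detects stereotypic swaying from
    cumulative trunk-root displacement, and evaluates automated coding
    against manual scoring with nocturnal time budgets, column-normalized
    confusion matrices, Kendall's coefficient of concordance, and Spearman
    rank correlations. Includes a synthetic-night simulator with known
    ground truth for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
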