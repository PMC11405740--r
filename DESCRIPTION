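Package: pupilclust
Title: Clustering Pupil-Size Dynamics Under Cognitive Load with Autonomic Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for an unsupervised analysis of pupillometry under escalating
    cognitive load with deceptive feedback. Builds per-participant trial-averaged
    pupil trajectories, normalizes and smooths them, screens outliers with an
    isolation forest, partitions participants with Euclidean k-means, and
    contrasts heart-rate-variability, electrodermal, respiratory, oculomotor and
    behavioral metrics between the resulting clusters using normality-gated
    tests with standardized and rank-based effect sizes. Includes a synthetic
    multimodal cohort generator with known archetype labels so the full pipeline
    is testable end to end without access to raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
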