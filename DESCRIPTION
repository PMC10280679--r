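Package: stressid
Title: Stress-Source Clustering and Anxiety-State Classification for Athlete Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies sources of psychological stress in athlete cohorts from
    tabular questionnaire scores. Implements a two-phase hierarchical clustering
    algorithm (a histogram-driven dividing phase that over-segments the cohort,
    followed by a bottom-up agglomerating phase that re-merges sibling
    subclasses), a three-unit Gaussian radial basis function network trained by
    gradient descent on its output weights, centers and widths for anxiety-state
    classification, weighted stress scoring with factor grouping, and a
    synthetic cohort generator with embedded worked-example fixtures. A small
    command-line surface wires the pieces into reproducible pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
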