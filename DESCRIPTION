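Package: tibclust
Title: Pathological Tibial-Rotation Typing by Genetic-Algorithm and K-Means Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to stratify subjects by physical attributes (age, weight,
    height) and classify tibial-rotation angles (RTER, RTIR, LTER, LTIR) as
    pathological or not, and to compare a real-coded genetic-algorithm
    clustering engine against a from-scratch K-Means baseline on that task.
    Includes a seeded synthetic-cohort generator that reproduces the
    categorical structure of the motivating 484-subject study, contingency
    and percentage tables, cluster-label alignment, and the study's
    min/max accuracy-rate statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
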