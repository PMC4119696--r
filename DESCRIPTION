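Package: fuzzygait
Title: Fuzzy-Set Similarity Measures and Gait-Signal Comparison
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Distance-based similarity measures for fuzzy sets on a shared
    discrete support, including a similarity measure for nonoverlapped
    (disjoint-support) point distributions built from per-sample complement
    masses, Lp-norm distances for high-dimensional records, and an
    end-to-end pipeline that compares multi-channel wearable gait
    recordings (walking, stair ascent, stair descent) across behaviors and
    subjects. Ships a seeded synthetic multi-sensor gait simulator so the
    full pipeline is testable without any recorded data, plus a small
    command-line interface for simulation and similarity tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
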