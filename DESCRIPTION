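Package: phytofg
Title: Phytoplankton Functional-Group Succession and Stability Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing freshwater phytoplankton communities at the
    functional-group level: classification of taxa into Reynolds/Padisak
    functional groups from a packaged trait catalog, conversion of cell counts
    to biovolume-based biomass, McNaughton dominance screening, per-day
    community succession rates, the average variation degree (AVD) stability
    index, and the supporting community-environment statistics (PCA,
    permutation Mantel tests, multivariate dispersion, and hierarchical
    partitioning of redundancy-analysis explained variance). Includes a
    seeded synthetic reservoir-survey generator so the whole pipeline is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
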