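Package: interologr
Title: Cross-Species IP-MS Interactome Filtering and Conserved-Interaction
    Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for cross-species comparison of immunoprecipitation
    mass-spectrometry (IP-MS) interactomes by spectral counting. Implements
    the full candidate-filtering cascade for bait-prey evidence
    (contaminant removal, control-IP subtraction, per-experiment
    identification thresholds, sticky-category removal), fly-human ortholog
    mapping by merged curated tables plus reciprocal best-three-hits
    sequence search, conserved-interactor (interolog) calling, replicate-
    averaged spectral-count quantification with stimulation fold changes
    and bait-subunit preference scores, and export of condition-annotated
    bait-prey networks. A synthetic-data generator with planted ground
    truth makes every stage testable end to end without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
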