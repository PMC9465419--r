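Package: reopanel
Title: Rank-Based Gene-Pair Panels for Lung Neuroendocrine Subtype Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Within-sample relative expression ordering (REO) classification of
    lung tumors into non-neuroendocrine, carcinoid, small-cell and large-cell
    neuroendocrine subtypes using a hierarchical panel of qualitative gene-pair
    signatures, together with the complete signature-discovery pipeline:
    consensus-clustering removal of samples discordant with their pathological
    label, differential-expression candidate selection, Fisher-exact mining of
    reversed gene pairs with false-discovery-rate control, apparent-accuracy and
    rank-difference scoring, and greedy de-redundant pair selection. Includes the
    published 92-pair diagnostic panel as a packaged resource and a synthetic
    expression-data generator with planted reversed-pair structure so every stage
    is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
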