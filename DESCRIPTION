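Package: nitrosaminer
Title: Mining, Curation and Classification of N-Nitrosamine Reaction Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for assembling and analysing reaction datasets in which the
    N-nitrosamine (NSA) functional group is consumed. Provides reaction-record
    input/output for delimited tables and JSON lines, stage-wise curation
    (structure sanitisation, single-step filtering, element balance checks,
    canonical deduplication), validation and heuristic generation of atom-atom
    mappings, reaction-center extraction at configurable depth with canonical
    layered encodings, detection of functional-group consumption, rule-based
    classification of nitrosamine substrates, reagents and transformations,
    attrition-funnel and classification-matrix reporting, and a seeded
    synthetic reaction-dataset generator with ground-truth labels for
    end-to-end pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineOB,
    igraph,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
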