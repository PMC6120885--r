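Package: craftr
Title: Causal Reasoning on Co-Expression Modules for Membrane-Receptor Target Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers disease-associated gene co-expression modules from
    case/control expression data and ranks cell-membrane receptors by their
    direction-specified influence over module sub-expression. Modules are
    built by Ward clustering of Spearman distances with elbow and pseudo
    F-index selection of the module count, tested for differential
    co-expression by gene-set permutation, related to a quantitative trait
    through module eigengenes and quantitative-trait-transcript analysis,
    and connected to membrane receptors through a signed two-layer
    receptor-to-transcription-factor-to-target regulome using causal sign
    composition, direction-specified hypergeometric enrichment against
    over- and under-expressed sub-modules, activator/inhibitor
    classification, and absolute and coverage-maximizing relative ranking.
    Includes seeded generators for expression, traits, regulomes and
    citation tables with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
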