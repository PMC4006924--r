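Package: sepsisconcord
Title: Cross-Model Concordance Analysis of Murine Sepsis Leukocyte Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for comparing two murine models of polymicrobial
    intra-abdominal sepsis (cecal ligation and puncture versus cecal slurry) at
    the blood-leukocyte transcriptome level. Provides unsupervised coefficient-
    of-variation filtering and supervised F-test gene selection on normalized
    log2 expression matrices, signed fold changes versus healthy controls,
    probe-set to gene-symbol collapsing with overlap accounting, leave-one-out
    cross-validation class prediction with a Monte-Carlo permutation null,
    genome-wide per-timepoint and maximum-change Pearson concordance between
    models, a distance-from-reference (DFR) transcriptome perturbation score,
    Fisher over-representation and directional activation Z scoring of gene
    sets, and a synthetic expression-matrix generator with known ground truth
    (controllable differential-expression fraction and between-model effect
    correlation) so every stage can be validated against simulation truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
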