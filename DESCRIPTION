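Package: devalign
Title: Aligning Tumor Expression Subgroups to a Developmental Continuum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for aligning molecular subgroups of medulloblastoma (WNT,
    SHH, Group 3, Group 4) to an ordered continuum of neural developmental
    reference samples (neural stem cells, neural progenitors, fetal germinal
    matrix, fetal brain). Implements probe-set level preprocessing (quantile
    normalization, a linear-scale detection-limit filter, probe-suffix and
    variance prefilters), PCA-based subgroup classification against a
    labelled reference cohort, group-centroid distance alignment in selected
    principal components, a developmental intersect differential-expression
    analysis with a step-wise exclusivity rule and a sigma-fold membership
    test for single-sample references, a weighted gene co-expression network
    (soft-threshold selection by scale-free fit, topological overlap modules,
    module eigengenes, eigengene cluster families, binary-trait association,
    and alignment-order scoring over candidate subgroup-to-stage maps),
    hypergeometric over-representation against GMT gene-set collections, and
    a seeded synthetic-cohort generator with planted ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    limma,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
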