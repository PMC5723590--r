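Package: betagrain
Title: Scale-Dependent Beta Diversity of Stem-Mapped Forest Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing how tree-species beta diversity and its
    underlying causes change with sampling grain inside a fixed-extent,
    fully stem-mapped forest plot. Communities are aggregated into square
    grains of several sizes; beta diversity is computed as the total
    variance of the Hellinger-transformed grains-by-species table, with
    local contributions (LCBD) per grain; spatial predictors are built as
    principal coordinates of neighbour matrices (PCNM / Moran eigenvector
    maps); and compositional variation is partitioned into environmental
    and spatial fractions by redundancy analysis with permutation-based
    forward selection of predictors. A synthetic-data module generates
    stem maps with known, tunable amounts of environmental filtering and
    dispersal limitation so that every stage of the pipeline can be
    validated against ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'grain-community.R'
    'beta-diversity.R'
    'betagrain-package.R'
    'community-sim.R'
    'env-field.R'
    'env-samples.R'
    'forward-select.R'
    'grain-design.R'
    'io.R'
    'ordination.R'
    'pcnm.R'
    'run-config.R'
    'pipeline.R'
    'scale-series.R'
    'stem-map.R'
    'topography.R'
    'upscale.R'
    'utils.R'
    'varpart.R'
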