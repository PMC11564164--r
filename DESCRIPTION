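Package: imgtx
Title: Imaging Transcriptomics of Gray-Matter Atrophy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Links voxel-based-morphometry group contrasts of gray-matter
    volume to spatial gene-expression profiles. Provides voxelwise GLM
    t-maps with Gaussian-random-field cluster correction, sphere-based
    regional t extraction at tissue-sample coordinates, first-component
    partial-least-squares association with bootstrap Z gene ranking,
    cross-contrast consistent-gene intersection, gene-wise Spearman
    statistics with Bonferroni correction, and hypergeometric
    over-representation with kappa-similarity term clustering. Includes a
    synthetic-data generator emulating donor microarray expression sets and
    smoothed volumetric cohorts with planted effects, so the full pipeline
    is testable end to end without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    fgsea,
    igraph,
    jsonlite,
    RNifti,
    stats,
    tools,
    utils,
    graphics
Suggests:
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
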