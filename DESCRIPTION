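Package: ecmap
Title: Eigenvector Centrality Mapping and Group Inference for
    Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxel-wise eigenvector centrality (EC) mapping of
    resting-state BOLD fMRI with three treatments of negative
    correlations ('add', 'abs', 'pos'), computed by power iteration
    with a matrix-free path that never materialises the voxel-by-voxel
    similarity matrix. Includes seed-based correlation follow-up,
    a within-subject flexible-factorial general linear model with
    difference-of-difference (interaction) contrasts, voxelwise t/z
    statistics with Benjamini-Hochberg FDR correction and cluster/peak
    tables, susceptibility-artifact intensity masking, framewise
    displacement motion QC, repeated-measures clinical score statistics,
    and a synthetic multi-subject BOLD study generator with planted
    network hubs and condition-dependent coupling for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
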