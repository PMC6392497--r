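Package: voxatlas
Title: Volumetric Atlas Toolkit for Transgenic Line Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with co-registered 3D expression volumes from
    transgenic line libraries on a shared larval zebrafish brain atlas grid:
    averaging, intensity normalization and masking of registered scans;
    texture-atlas montage export; a bit-packed, block-fragmented voxel
    occupancy index for fast 3D spatial search across hundreds of lines;
    prediction of Gal4 x Cre intersectional expression; cell-body coverage
    statistics and per-voxel line-count maps; 20 micron binned expression
    vectors with mirrored-hemisphere pooling and region means; stratified
    neuron-count estimation from density bins; and deconvolution of pooled
    integration-site sequencing via combinatorial pool design. Includes a
    synthetic phantom-brain generator so every stage can be exercised without
    the original imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    png,
    yaml,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
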