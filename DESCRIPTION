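Package: MSIbackfit
Title: Bin-Train-Backfit Segmentation of Low-Count ToF-SIMS Hyperspectral Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Unsupervised segmentation of extremely low-count hyperspectral
    time-of-flight secondary ion mass spectrometry (ToF-SIMS) images. A
    parametric low-dimensional embedding (a fuzzy neighborhood graph optimized
    by a neural-network encoder under a cross-entropy objective) is trained on
    a pixel-binned cube, where counting statistics are adequate, and then
    backfitted to the full-resolution unbinned cube, so that cluster
    structure is recovered without sacrificing lateral resolution. Includes
    pixel-domain and mass-domain (transposed) clustering with a noise label,
    cluster-characteristic spectrum reconstruction, a deposition-sequence
    statistic for overlapping fingermarks, a binning-level sweep, sparse cube
    input/output with imzML import, and a synthetic overlapping-fingermark
    phantom generator with analytic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    grDevices,
    Matrix,
    data.table,
    jsonlite,
    xml2,
    png,
    cluster,
    mclust
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
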