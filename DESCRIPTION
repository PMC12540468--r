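Package: spotmatch
Title: Landmark-Based Registration and Integration of Spatial
    Transcriptomics and Mass-Spectrometry-Imaging Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Point-to-point registration of hexagonal spatial-transcriptomics
    spot arrays (Visium-style) with spatial-metabolomics raster pixels
    (DESI and related mass-spectrometry imaging). Converts both modalities
    into a unified micrometre frame, estimates a similarity transform
    (scale, rotation, translation) from at least six landmark pairs with
    robust outlier filtering, and assigns transformed pixels to their
    nearest spot to build a spot-by-metabolite intensity matrix. Downstream
    tools cover TIC normalization, OPLS-DA with VIP scores and
    cross-validated R2X/R2Y/Q2 diagnostics, permutation testing, the
    VIP > 1 and p < 0.05 differential-metabolite rule, threshold-based
    per-spot cell-type designation from deconvolution proportions, and
    classification of metabolite trends along pseudotime branches. A
    synthetic-section generator with known ground truth supports fully
    reproducible validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    xml2,
    optparse
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
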