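Package: taxvis
Title: Three-Level Taxonomic Visual Categorization Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Feature extraction and evaluation for hierarchical
    (superordinate / basic / subordinate) visual object categorization.
    Implements global Fourier-spectrum features that separate artificial
    from natural objects, a 32-dimensional shape descriptor combining
    standardized image moments with Zernike moment magnitudes for
    animal/plant discrimination, and per-concept ("conceptual") versus
    pooled ("flat") eigenspace projections for subordinate-class
    recognition, together with a seeded synthetic image generator, a
    fuzzy-clustering and repeated-split linear-SVM evaluation harness,
    and a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    jpeg,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
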