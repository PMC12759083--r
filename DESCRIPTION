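Package: mitosense
Title: Quantitative Pipelines for Mitophagy Reporter Screens, Flow
    Cytometry, Imaging and Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tested implementations of the quantitative procedures used in
    FACS-bin CRISPRi reporter screens of the PINK1-Parkin mitophagy pathway
    and their companion assays: guide-level screen scoring with Bonferroni
    correction, gene scores and six-screen hit classification; single-cell
    flow-cytometry statistics (reporter degradation, control normalization,
    membrane-potential normalization, mt-Keima mitophagy gating with
    spillover compensation, quadrant analysis); mask-based per-mitochondrion
    image quantification with a pixel-randomization Pearson colocalization
    null; proteomics differential abundance with Benjamini-Hochberg FDR,
    non-mitochondrial-median normalization and presequence annotation; and
    synthetic-data generators with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    mgcv,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    DESeq2,
    EBImage,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
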