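Package: ihcquant
Title: Whole-Slide Immunohistochemistry Quantification for Tumor-Adjacent Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies immunohistochemistry (IHC) whole-slide scans of
    tumor-adjacent cortex: per-slide stain-color reference estimation,
    angle-based pixel classification into hematoxylin / immunostain /
    unstained, nucleus and particle segmentation, disk-kernel density
    heatmaps in objects per square millimetre, rigid coregistration of
    serial sections on tissue background masks, annotation-polygon masks,
    and cortex-restricted per-pixel density tables. Includes a synthetic
    brightfield slide and cohort generator with exported ground truth,
    a semiquantitative neuropathology scoring model (CERAD, Braak groups,
    Alzheimer's disease neuropathological change categories, amyloid
    precursor protein and axonal-injury scores, Cohen's kappa), and the
    correlation statistics used on density vectors (Kendall tau-b,
    Pearson, Shapiro-Wilk gating, Fisher's exact test, ANOVA with
    Bonferroni-adjusted pairwise comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    xml2,
    yaml,
    png,
    tiff,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
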