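Package: fundusCDR
Title: Optic Disc and Cup Segmentation and Cup-to-Disc Ratio Screening for
    Retinal Fundus Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automatic glaucoma-screening pipeline for colour retinal
    fundus photographs. Blood vessels are extracted with a morphological
    black top-hat on the green channel and removed by diffusion inpainting;
    the optic disc is localized by interval Type-II fuzzy-entropy multilevel
    thresholding (optimized with Differential Evolution) and segmented with a
    level-set active contour (with a double level-set path for low-quality
    images); the optic cup is segmented by a four-loop thresholding cascade
    with automatic error detection and circular Hough approximation.
    Horizontal and vertical cup-to-disc ratios (HCDR/VCDR) are computed from
    extreme-pixel extents. The package also implements a multi-grader
    evaluation protocol (per-image standard deviations, mean-SD outlier
    thresholds, image-elimination rules, accuracy and pairwise-agreement
    tables) and a synthetic fundus phantom and grader-marking generator with
    known ground truth, so every stage is testable without clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
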