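Package: SonoQuant
Title: Quantitative B-Mode and Color-Doppler Ultrasound Analysis of
    Peripheral Nerve and Muscle
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Pixel-based quantification of high-resolution
    neurosonography frames. Computes the fascicular ratio (FR),
    cross-section area (CSA) and cross-section ratio (CSR) from B-mode
    images, and the vascular ratio (VR), muscle perfusion ratio (MPR)
    and high-velocity flow proportion from color-Doppler frames by
    decomposing the RGB color overlay into four velocity/direction
    classes with saturating channel subtraction, merging them into
    direction-independent maximum projections, and selecting signal by
    Kapur maximum-entropy thresholding and particle analysis. Includes
    a synthetic speckle-frame generator with known ground truth and a
    cohort statistics layer (normality-gated ANOVA/Tukey or
    Kruskal-Wallis/Dunn, Pearson correlation) so the full pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    png,
    tiff,
    jsonlite,
    pracma,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
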