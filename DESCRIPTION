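Package: glioscan
Title: Brain MRI Tumor Segmentation and Texture-Based Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An image-analysis pipeline for detecting tumor regions in 2D
    brain magnetic-resonance images. Provides grayscale image input/output
    (PNG, TIFF and single-frame DICOM), median-filter denoising with
    PSNR/MSE fidelity metrics, seeded region-growing segmentation with
    binary morphological cleanup and tumor area measurement, multilevel 2D
    discrete wavelet decomposition, gray-level co-occurrence matrix (GLCM)
    texture features (contrast, correlation, energy, homogeneity, entropy),
    and a probabilistic neural network (Parzen-window) classifier that
    labels images as normal or abnormal. A synthetic brain-phantom
    generator with ground-truth masks makes every stage testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    png,
    tiff,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
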