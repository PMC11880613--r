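Package: xaimri
Title: Ensemble Dual-Modality 3D Brain Tumor Segmentation with Explainable Heat Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multimodal 3D MRI brain-tumor segmentation in the BraTS
    mold: a seeded multimodal phantom generator with nested tumor sub-regions,
    NIfTI ingestion of BraTS-layout subjects, region-of-interest cropping and
    resizing to a standard cubic grid, a configurable 3D U-Net with
    modality-stacked inputs trained by mini-batch Adam with early stopping,
    feature-level ensembling of two pre-trained dual-modality models through a
    fusion convolution, the six standard voxel-wise segmentation metrics
    (accuracy, mean IoU, Dice, precision, sensitivity, specificity), and 3D
    Grad-CAM relevance volumes with slice overlay rendering. Convolution
    kernels and their backward passes are implemented in C++.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
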