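Package: NeuroTexNet
Title: Texture-Based Multiclass Brain-Tumor Image Classification with
    Metaheuristic Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale, fully seeded implementation of a multi-stage
    pipeline for classifying brain-tumor classes (meningioma, glioma,
    pituitary) from 2-D grayscale image slices: median-filter denoising and
    morphological skull stripping, rotation/flip augmentation, adaptive
    Canny edge detection with a Mayfly-style swarm adjustment of the
    gradient field, spatial gray-level dependence matrix (SGLDM/GLCM)
    texture features over the segmented region of interest, wrapper feature
    selection by an enhanced chimp optimization algorithm, and a
    depth-configurable residual network with a softmax head.  A seeded
    synthetic brain-phantom generator with known ground truth replaces
    external MRI datasets, so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
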