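Package: aaawall
Title: Outer-Wall Segmentation and Membrane Wall-Stress Analysis of
    Abdominal Aortic Aneurysms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for image-based biomechanical analysis of abdominal
    aortic aneurysms (AAA). Provides a patch-based dilated U-Net for
    outer-wall mask segmentation trainable at phantom scale, closed
    non-uniform rational B-spline (NURBS) refinement of mask boundaries
    with programmatic control-point editing, lofting of contour stacks
    into physically scaled triangular surface meshes, an inverse
    membrane-equilibrium solver that estimates the Cauchy wall-stress
    field from the imaged geometry and intraluminal pressure without
    material properties, biomechanical summary statistics (99th
    percentile, mean and spatially averaged wall stress), segmentation
    quality metrics (Dice, IoU, MCC, 95th-percentile Hausdorff
    distance), and a synthetic fusiform-aneurysm phantom generator with
    analytic ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    Matrix,
    png,
    Rcpp,
    RNifti,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
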