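Package: vertseg
Title: Semi-Automatic Vertebral Body Segmentation in Sagittal Spine Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automatic segmentation of vertebral bodies in 2-D sagittal
    lumbar-spine magnetic resonance images. Starting from a single user-drawn
    rectangular region of interest (ROI) on one vertebral body, the pipeline
    detects the remaining vertebral bodies by normalized cross-correlation with
    iterative peak search and neighborhood suppression, refines each ROI by
    Canny edge extraction, Hough-transform rotation estimation and
    projection-profile boundary adjustment, and segments each body with a
    hybrid of minimum-cost graph paths (superior/inferior boundaries) and
    intensity-cluster line rules (lateral boundaries). Includes a synthetic
    spine-phantom generator with exact ground truth, and evaluation tools
    (Dice similarity coefficient, voxel counts, physical volumes, detection
    error).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    RNifti,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
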