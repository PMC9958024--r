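Package: cbctreorient
Title: Landmark-Free PCA Reorientation of Serial CBCT Head Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns a reproducible, individualized global axis to serially
    captured cone beam computed tomography (CBCT) head volumes without
    anatomical landmarking. Bone is segmented by Otsu thresholding, the nose
    tip is located automatically as the anterior convex-hull apex inside a
    naso-orbital region of interest, serial volumes are arranged on the nose
    tip, and an orthonormal head frame is estimated by principal component
    analysis of a 35 mm spherical region around the tip. Includes a Hausdorff
    distance evaluation protocol on forehead surfaces, k-medoids clustering of
    clinical asymmetry magnitude, a synthetic head-phantom generator with
    exact ground truth, and minimal readers and writers for DICOM series,
    NIfTI-1 and NRRD volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    FNN,
    cluster,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
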