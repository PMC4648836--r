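Package: tunnelmetry
Title: Bone Tunnel Diameter Measurement from CT Volumes and Triangle Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the diameter of drilled bone tunnels (such as anterior
    cruciate ligament reconstruction tunnels) from computed tomography volumes
    and from triangle-mesh surface models. Implements four measurement methods:
    an orthogonal-distance best-fit cylinder over the whole tunnel length, a
    circle fitted to the tunnel wall in the transverse section at mid-length of
    an automatically extracted centerline, a ray-cast wall-thickness method, and
    the clinical two-dimensional CT method (mean of straight-line widths in the
    axial, coronal and sagittal planes through the tunnel mid-point). Includes
    threshold-based bone segmentation, morphological tunnel-cavity extraction,
    iso-surface mesh generation, a synthetic CT phantom generator with known
    drill diameters for validation, and intraclass correlation ICC(2,1)
    agreement statistics with F-based confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
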