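Package: dermascan
Title: Whole-Body Scan Reconstruction and Orthorectification of Skin
    Lesion Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds a triangle-mesh model of the human body from multi-view
    depth scans acquired by a rotating-arm scanner (cropping, voxel
    downsampling, normal estimation, pairwise ICP registration with
    loop-closure pose-graph optimization, statistical outlier removal,
    moving-least-squares smoothing, and implicit surface reconstruction),
    relates high-resolution skin photographs to the mesh through
    triangle-index and barycentric software rendering, and locally
    orthorectifies image patches on the surface tangent plane so that the
    size and proportions of skin nevi can be measured in true scale.
    Includes a fully synthetic scan-session generator (phantom surface with
    printed circular markers, virtual cameras and depth scanners) and
    marker-morphology metrics for quantitative assessment of the
    rectification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    EBImage,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
SystemRequirements: C++17
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
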