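Package: curvomesh
Title: Tensor-Voting Curvature Estimation on Membrane Surfaces from Voxel Segmentations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Robust estimation of surface normals, principal directions and principal
    curvatures on triangle meshes extracted from binary voxel segmentations, as used for
    membrane morphology analysis in cryo-electron tomography. A signed single-layer surface
    is extracted from a filled compartment segmentation, mapped to a spatially embedded
    graph of triangle centroids for geodesic neighborhoods and border filtering, and
    per-triangle normals and curvatures are estimated by tensor voting (regular, augmented
    and surface-sampling variants). Includes synthetic benchmark surfaces with analytic
    ground truth (noisy plane, quantization-noise and smooth spheres, torus, cylinder),
    error metrics and cumulative-histogram accuracy summaries, plus MRC volume and VTK XML
    PolyData (.vtp) input/output.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    xml2
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
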