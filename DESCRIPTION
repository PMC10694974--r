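Package: mycomat
Title: Microstructure and Material Properties of Fungal Mycelium Composites
Version: 0.1.0
Authors@R:
    person("Maintainer", "mycomat", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of fungal mycelium-hemp composite
    materials. Implements a micro-computed-tomography segmentation
    pipeline separating lignocellulosic substrate particles (hemp
    shives) from the fungal hyphal network, morphometry of the
    segmented network (3D skeletonization, Euclidean-distance-transform
    diameter, total length, branch and tip counts, distance-shell
    branching-frequency profiles), EN-norm material-property
    calculators (compression, three-point bending, transverse tension,
    raw density, soak swelling, water vapour diffusion, thermal
    conductivity, small-flame flammability classing), and a synthetic
    voxel-phantom and test-record generator with exact ground truth so
    that every stage is testable without proprietary scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
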