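Package: radsym
Title: Landmark-Free Morphometric Analysis of Bilateral Bone Symmetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Landmark-free morphometric pipeline for quantifying left-right
    mirror symmetry and population-level shape variability of 3D bone surface
    meshes, modelled on the distal radius. Provides triangulated-mesh data
    structures and I/O (VTK legacy PolyData, PLY, STL), isosurface extraction
    from binary label volumes, quadric-error decimation, rigid preprocessing
    (mirroring, principal-axis alignment via Rodrigues' rotation, landmark
    least-squares alignment, plane crops, articular-surface isolation),
    control-point diffeomorphic registration by geodesic shooting with a
    varifold surface attachment, deterministic atlas (mean shape) estimation,
    signed correspondence-distance statistics, kernel PCA of deformation
    momenta with Shapiro-Wilk, Kruskal-Wallis and Welch group testing, and a
    seeded generator of distal-radius-like phantom cohorts with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
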