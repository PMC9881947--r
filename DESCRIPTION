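Package: vascox
Title: Image-to-Physics Oxygen Transport in Microvascular Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts 2D images of microvascular networks into conforming
    multi-domain triangular finite-element meshes and predicts steady-state
    oxygen concentration in both the vessel network and the surrounding
    tissue. Vessel components are classified as inlet-connected or
    disconnected, meshes are built by constrained Delaunay triangulation of
    the region boundaries with graded element sizing, and the stationary
    diffusion(-reaction) equation is solved with a Galerkin P1 finite-element
    method. Tissue consumption may be zero-order or Michaelis-Menten, the
    latter solved by Picard iteration. Network-performance metrics (inlet
    flux, vascular oxygen, oxygen delivery, end-to-end connectivity, vessel
    coverage) are computed per image, and a seeded synthetic vascular-network
    generator plus finite-difference and closed-form oracles make the whole
    pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Matrix,
    Rcpp,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deldir,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
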