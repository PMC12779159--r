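Package: ciliaflow
Title: Tissue-Scale Ciliary Stokes Flow, Tracer Transport and Mixing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates the three-dimensional viscous flow driven by beating
    cilia over a no-slip epithelial surface and the transport and mixing of
    passive tracer particles it induces.  Each cilium is a rigid rotating
    rod of phase-dependent length whose motion is prescribed; the flow is
    computed with regularized Stokeslets distributed along the rods together
    with an exact image system that enforces the no-slip condition on the
    wall.  Tools are provided to build single cilia clusters, linear cluster
    arrays with variable spacing, random tissue patches of given ciliary
    density and imposed metachronal phase lags; to advect tracers with a
    fourth-order integrator; and to quantify transport (centre of mass),
    mixing (nearest-neighbour mixing number), and spatial organization
    (Ripley's K with the complete-spatial-randomness crossing radius,
    cycle-averaged velocity and vorticity fields).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
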