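Package: angiomech
Title: Meshless Simulation of Mechanically Regulated Sprouting Angiogenesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates sprouting angiogenesis on a two-dimensional tissue
    domain discretised with the Radial Point Interpolation Method (RPIM).
    Steady-state VEGF diffusion and plane-stress elastostatics are solved on
    a shared nodal cloud using multiquadric radial basis shape functions;
    hydrostatic pressure applied over a circular region modulates the local
    VEGF diffusion coefficient, and endothelial tip cells migrate up the
    VEGF gradient with order-dependent branching that is intensified under
    compression. Ships the four example scenario presets, capillary network
    morphometrics (total vessel length, branch counts, percent of control),
    and CSV/JSON/VTK export.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    methods,
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
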