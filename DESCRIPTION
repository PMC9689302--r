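Package: ijvflow
Title: Immersed-Boundary Hemodynamics of a Stenosed Internal Jugular Vein
    with a Flexible Two-Leaflet Valve
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-dimensional pulsatile blood-flow simulation of an internal
    jugular vein carrying a nozzle-like stenosis near its inlet and a
    hyperelastic two-leaflet venous valve downstream.  The fluid is solved
    with a fractional-step (pressure-projection) scheme on a staggered
    Cartesian grid with masked solid cells, optionally closed with a
    Wilcox-type k-omega eddy-viscosity model.  The valve leaflets follow a
    compressible neo-Hookean constitutive law, reduced to an inertial
    elastic fiber (stretching and bending), and are coupled to the fluid by
    a regularized-delta immersed-boundary method.  Post-processing
    quantifies stenotic flow disturbances: per-section maximum-velocity
    profiles, reverse-flow (separation) area, jet asymmetry, and asymmetric
    leaflet bending.  Includes the four standard stenosis severities
    (0, 30, 60, 75 percent), a grid-independence utility and VTK/CSV export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: Matrix, methods, stats, tools, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), igraph, knitr, rmarkdown, optparse
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
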