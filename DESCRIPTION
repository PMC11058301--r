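Package: hemoflow
Title: Two-Fluid Finite-Volume Simulation of Blood Flow in Microvessels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-fluid (Eulerian-Eulerian) continuum model of blood flow in
    microvessels, treating plasma as a Newtonian liquid and the red-blood-cell
    population as a second, shear-thinning, hematocrit-dependent continuum
    coupled to the plasma by interphase drag, Saffman shear-lift and spin-lift
    forces under a shared pressure. Includes a steady-state collocated
    finite-volume solver (SIMPLE-type pressure-velocity coupling with
    Rhie-Chow momentum interpolation) on body-fitted structured grids for
    planar and axisymmetric half-domains, parametric generators for a
    sudden-expansion channel and a cosine-profile stenosed vessel,
    post-processing of wall shear stress, cross-section profiles,
    recirculation extent and cell-free and cell-rich layer metrics, legacy
    VTK and CSV output, and scripted parameter sweeps over inlet velocity and
    inlet hematocrit with an analytic (Poiseuille) verification suite.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    ggplot2,
    generics,
    tibble,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
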