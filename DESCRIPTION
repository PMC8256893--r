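Package: eitmesh
Title: Electrical Impedance Tomography on Brachytherapy Needle Resistor Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forward simulation and inverse reconstruction for electrical
    impedance tomography (EIT) performed with brachytherapy needles inserted
    through a standard 13x13 template. The medium is discretized as a square
    resistor mesh; nodal voltages under adjacent-pattern current injection are
    obtained from Kirchhoff-current-law network analysis, and the internal
    resistance distribution is recovered with a Marquardt-damped Modified
    Newton-Raphson (Gauss-Newton) solver using adjoint Jacobian sensitivities.
    Includes a synthetic phantom generator emulating conductive and resistive
    inclusions, absolute and frequency-difference imaging modes, and rendering
    of [0,1]-normalized tomograms.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
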