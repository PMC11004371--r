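Package: pvloopva
Title: Closed-Loop Pressure-Volume Simulation of Vascular Aging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A lumped-parameter, closed-loop cardiovascular simulator built
    around four time-varying-elastance chambers, a proximal aortic-arch
    Windkessel element, five parallel distal systemic compartments and a
    two-compartment pulmonary loop, together with the full pressure-volume
    analysis stack used in vascular-aging studies: simulated vena caval
    occlusion (VCO), beat segmentation, per-beat metrics (stroke work,
    pressure-volume area, mechanical efficiency, dynamic arterial
    compliance) and linear fits of the ESPVR, preload recruitable stroke
    work, dP/dt_max-EDV and PVA-EDV relations across graded aortic
    compliance and pacing rate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
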