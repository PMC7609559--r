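Package: coarctflow
Title: Rest-Versus-Exercise Hemodynamics of Aortic Coarctation from
    MRI-Ergometry Measurements and Reduced-Order CFD
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the hemodynamic response to physical exercise
    in aortic coarctation. Ships a transcribed 20-patient MRI-ergometry
    reference cohort (cuff pressures, heart rate, stroke volume, peak-systolic
    ascending and descending aortic flow, and CFD-derived descriptors at rest
    and during exercise), a seeded synthetic-cohort generator that emulates
    velocity-encoded MRI measurement planes, a parametric axisymmetric
    stenotic-aorta geometry with graded structured meshing, measurement-driven
    boundary conditions (inlet velocity-profile mapping, Murray's-law branch
    partitioning, arch sink band), a steady laminar finite-volume
    Navier-Stokes solver with Carreau-Yasuda shear-thinning rheology, the
    clinical descriptors computed from its fields (transstenotic pressure
    gradient, surface-averaged wall shear stress, secondary flow degree,
    normalized flow displacement, cardiac and stroke-volume indices), and
    normality-routed paired rest-versus-exercise cohort statistics including
    the 20 mmHg intervention-threshold classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
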