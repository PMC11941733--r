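Package: aortafem
Title: Finite-Element Wall Stress and Rupture-Risk Assessment for Abdominal Aortic Aneurysms
Version: 0.1.0
Authors@R:
    person("aortafem", "maintainers", email = "maintainers@aortafem.invalid", role = c("aut", "cre"))
Description: An end-to-end, fully scripted pipeline for the structural
    evaluation of abdominal aortic aneurysms (AAA): parametric synthesis of
    fusiform aneurysm geometries and noisy voxel phantoms, threshold
    segmentation and isosurface reconstruction of the lumen, extrusion of a
    uniform-thickness wall into a conforming tetrahedral mesh, a linear
    isotropic elastostatic finite-element solver (constant-strain tetrahedra)
    under incremental lumen pressure with fixed inlet and outlet, von Mises
    stress / equivalent strain / displacement post-processing, and a
    rupture-risk probability obtained from the pressure-strain modulus through
    a saturating risk curve calibrated by least squares on a published
    12-case cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    grDevices,
    methods,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
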