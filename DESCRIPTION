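Package: egmeye
Title: Equilibrium-Gap Identification of Corneal Material Parameters from
    Virtual Non-Contact Tonometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Update-free inverse identification of anisotropic hyperelastic
    cornea material parameters (penalty bulk modulus K, shear modulus mu,
    collagen fiber stiffness k1 and fiber nonlinearity k2) from full-field
    displacement data via the equilibrium gap method. The internal-force
    vector of the fiber-reinforced constitutive model is exactly linear in
    (K, mu, k1) at fixed k2, so the identification reduces to a convex 3x3
    least-squares problem per deformation state; the nonlinear parameter k2
    is found by a nested grid search minimizing the relative scatter of the
    state-wise linear parameter sets. The package ships its own reduced
    finite-element model of the anterior eye (hexahedral elements, fluid
    cavity, stress-free reference geometry recovery) used to generate
    synthetic virtual-tonometry records with keratoconus-like fiber
    degradation, a noise study, and a mechanical morphing module that
    reconstructs representative 3D displacement fields from 2D deformation
    contours.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
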