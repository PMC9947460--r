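Package: orbitfem
Title: Axisymmetric Finite-Element Biomechanics of Orbital Fat Swelling and the Eye
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Axisymmetric, geometrically nonlinear finite-element model of the
    human eye and orbit under microgravity-induced swelling of the orbital fat.
    Tissues are incompressible neo-Hookean solids with multiplicative hygroscopic
    swelling; intraocular pressure is generated by vitreous swelling from an
    inversely identified zero-stress configuration; the sclera slides without
    friction against the orbital fat; extraocular-muscle tension follows a
    passive rectus stretching law. The package provides the staged loading
    protocol (zero-stress identification, residual stress, terrestrial baseline,
    swollen microgravity state), ocular biometric outputs (proptosis, axial
    length, peripapillary arc length, posterior radius of curvature by Pratt
    circle fit) and drivers for sensitivity studies over intracranial pressure,
    scleral stiffness and orbital anatomy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    rlang,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
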