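Package: skindamage
Title: Anisotropic Damage Constitutive Modelling of Skin Under Uniaxial Tension
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Invariant-based anisotropic hyperelastic constitutive model for
    human and animal skin with Volokh-type energy limiters describing
    damage-induced softening of both the collagen-fibre network and the
    ground-substance matrix. Extends the Gasser-Ogden-Holzapfel (GOH)
    fibre-dispersion model with nine material parameters, and provides
    forward uniaxial Cauchy-stress prediction for two orthogonal skin
    specimens, fibre-break-limit detection with brittle/ductile damage
    classification, analytic parameter sensitivities with group ranking,
    inverse multi-start bounded least-squares estimation of the parameters
    from paired uniaxial stress-stretch data, a synthetic uniaxial
    experiment generator, parameter presets for published human and animal
    skin cases, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
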