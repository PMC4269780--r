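Package: airwaymech
Title: Multiscale Mechanics of Dynamic Bronchoconstriction in Intact Airways
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates an intact airway as an incompressible, fiber-reinforced,
    strain-stiffening thick-walled elastic cylinder whose contractile hoop
    fibers are driven by Huxley-Hai-Murphy (HHM) actomyosin cross-bridge
    kinetics. Prescribed transmural-pressure waveforms drive a quasistatic
    wall equilibrium that is two-way coupled to the sliding-filament
    population dynamics, reproducing static pressure-radius and effective
    stiffness curves, tidal pressure-radius loops with hysteresis, and
    bronchodilation protocols, including airway-wall remodeling variants.
    Includes nonlinear least-squares fitting of the passive constitutive
    parameters to pressure-radius data, logistic smoothing of experimental
    style curves, and seeded synthetic-data generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
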