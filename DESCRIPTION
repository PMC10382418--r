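Package: aimsim
Title: Ab Initio Multiple Spawning Dynamics on Vibronic Coupling Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Full and ab initio multiple spawning (FMS/AIMS) nonadiabatic
    quantum dynamics for analytic linear vibronic coupling (LVC) model
    Hamiltonians.  Trajectory basis functions (frozen Gaussians) are
    propagated classically on adiabatic surfaces, coupled through analytic
    Gaussian matrix elements under the zeroth-order saddle-point
    approximation, and the basis grows adaptively through the spawning
    algorithm.  Includes Wigner sampling of initial conditions, a
    numerically exact split-operator grid propagator as reference, and a
    one-at-a-time parameter sensitivity layer (signed relative population
    deviations summarised by Scott-rule kernel density estimates).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
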