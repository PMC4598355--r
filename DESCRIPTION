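Package: finwalk
Title: Data-Driven Stochastic Modelling of Zebrafish Locomotion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the spontaneous swimming of individual
    zebrafish (Danio rerio) as a persistent turning walker with variable
    speed. Provides trajectory input/output and kinematic derivation
    (speed, signed turning speed, heading), segmentation of swimming bouts
    by speed thresholding, exact maximum-likelihood estimation for
    regularly sampled Ornstein-Uhlenbeck processes, LOESS-plus-exponential
    fitting of the wall-avoidance response, an Euler-Maruyama simulator of
    the coupled speed/turning-speed stochastic differential equations in a
    bounded rounded-corner arena, and validation statistics
    (autocorrelation times, joint speed-turn densities, occupancy maps).
    Ships the calibrated parameter sets for eight fish together with the
    global weighted means used for simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
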