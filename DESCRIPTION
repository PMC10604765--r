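Package: bsiflow
Title: Blood Speckle Imaging Velocimetry and Wall Shear Stress Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and quantification chain for ultrasound blood speckle
    imaging (BSI). Generates synthetic speckle cine loops with analytically
    known pulsatile flow fields (uniform, parabolic channel, top-hat jet, and
    anteriorly deflected stenotic jet with posterior recirculation), estimates
    in-plane blood velocity and a [0,1] match-confidence channel by
    normalized-cross-correlation block matching with parabolic sub-pixel
    refinement, and derives clinical hemodynamic indicators: velocity and
    shear-stress profiles, signed wall shear stress series, time-averaged wall
    shear stress (TAWSS), the oscillatory shear index (OSI), peak-velocity
    traces, and simplified-Bernoulli pressure gradients.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
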