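Package: mitostereo
Title: Virtual Stereology for Quantitative Electron Microscopy of
    Microsporidian Mitosomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and design-based estimation tools for quantitative
    electron microscopy of very small organelles. Generates synthetic 3D
    microsporidian meront cells (spherical nucleus, two spindle pole bodies,
    dumbbell-shaped mitosomes with tether assignments), cuts them into
    virtual serial sections, tomographic slices, superslices and ministacks,
    and implements the classical stereological estimators: point-grid
    counting, Cavalieri volumes, overprojection (Holmes effect) correction,
    appearance-based particle counting, volume and number densities, star
    volume, and coefficients of error. Companion inference tools cover
    organelle partitioning statistics across the two spindle pole bodies,
    contingency tests, correlation tables and a spindle-pole-body occupancy
    model. The acceptance surface is parameter recovery on simulated ground
    truth, so every estimator can be validated without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
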