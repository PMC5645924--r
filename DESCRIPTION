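Package: deglukin
Title: Swallowing Kinematic Analysis from Videofluoroscopic Landmark Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scriptable analysis of swallowing kinematics from manually marked
    videofluoroscopic swallowing study (VFSS) landmarks. Transforms per-frame
    pixel marks into a moving anatomical reference frame anchored at the C2 and
    C4 cervical vertebrae, calibrates a millimetre scale from a reference
    object, smooths trajectories (moving average, Savitzky-Golay, LOWESS/LOESS
    families, global polynomial), computes finite-difference velocities,
    tilt angles and opening distances, and extracts peak spatiotemporal
    parameters and event-based transit times. Includes a mechanism-based
    phantom simulator (slider-crank and belt-pulley) with analytic ground
    truth for end-to-end validation, and rater-agreement statistics
    (intraclass correlation with F-based confidence intervals, Pearson
    correlation, Bland-Altman limits of agreement). A small command-line
    interface exposes simulate, analyze and reliability subcommands.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    broom,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
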