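Package: windsock
Title: Tethered DNA Nanotube Flow Sensors: Langevin Dynamics, Calibration, and Attachment Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models micron-scale DNA nanotubes anchored by their seed end to a
    surface as "windsock" flow sensors. Provides the exact Fourier-series
    Poiseuille solution for wall shear stress in rectangular microchannels,
    overdamped Langevin (Brownian dynamics) simulation of a tethered rigid rod
    rotating under flow-induced torque and thermal noise with its von Mises
    stationary law, the total-rotation-angle statistic with shear-stress
    calibration and inversion, synthetic fluorescence time-lapse rendering with
    a maximum-time-projection measurement pipeline, receptor attachment
    kinetics with exponential surface-persistence fitting, and
    point-pattern colocalization statistics with a randomized-placement null.
    All analyses are exercisable on the package's own synthetic data
    generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
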