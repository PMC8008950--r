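Package: arterymech
Title: Biaxial Pressure-Myograph Analysis of Arterial Wall Mechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis of biaxial inflation-extension tests of small arteries
    recorded on a pressure myograph: estimation of the in vivo axial stretch
    (IVS) from force-length tests at multiple pressures, loaded geometry from
    outer-diameter sweeps via wall incompressibility, circumferential and
    axial Cauchy wall stresses, tangent moduli, an axial-force quality-control
    exclusion rule, and cohort-level statistics (two-way ANOVA over
    pressure-matched curves, exact Mann-Whitney tests, Holm-Sidak
    adjustment).  A forward simulator built on a four-fiber-family
    constitutive model generates synthetic instrument recordings with known
    ground truth for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
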