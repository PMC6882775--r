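Package: tidalRD
Title: Breath-by-Breath Tidal Recruitment Analysis of Dynamic Lung CT
    During Assisted Spontaneous Breathing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies cyclic (tidal) recruitment and derecruitment of
    lung tissue from dynamic computed-tomography slice sequences acquired
    during assisted spontaneous breathing over a positive end-expiratory
    pressure (PEEP) ramp.  Provides Hounsfield-unit aeration
    compartmentalization of masked CT slices, breath detection and
    volume integration from ventilatory tracings, single-compartment
    equation-of-motion multilinear fitting of respiratory mechanics,
    resistive-corrected maximal transpulmonary pressure, diaphragm
    electrical activity (EAdi) statistics, CT-to-spirometry clock
    synchronization, per-breath recruitment/derecruitment normalization,
    and a nonparametric statistical battery (Kruskal-Wallis with
    Dunn-Sidak post hoc, one- and two-tailed Ansari-Bradley dispersion
    tests, polynomial PEEP-response regressions).  A deterministic
    breathing simulator and dynamic CT lung phantom with per-region
    opening/closing pressures supply ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
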