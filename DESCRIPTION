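Package: melanophot
Title: Alpha-Opic Photometry, Silent-Substitution Metamer Design and
    Melanopsin Dose-Response Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the non-visual (melanopsin-mediated)
    effects of light. Computes CIE S 026 alpha-opic irradiances, equivalent
    daylight illuminances (EDIs) and daylight efficacy ratios from spectral
    power distributions; solves the silent-substitution problem for
    multiprimary light sources (cone-matched metamer pairs with maximal
    melanopsin contrast); preprocesses eye-tracker pupillometry (confidence
    and plausibility filtering, median binning, quality exclusion); converts
    corneal photometry plus pupil geometry to conventional and alpha-opic
    retinal trolands; and fits log-dose regressions of pupil size and evening
    melatonin suppression against corneal (melanopic EDI) versus retinal
    (melanopic troland) dose. Includes a synthetic-study generator emulating
    a 4-intensity x 2-condition x 18-subject metameric light exposure design
    with known ground truth for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
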