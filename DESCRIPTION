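Package: coldclock
Title: Circadian Rhythm Simulation and Quantification Under Hypothermia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying cold-induced suspension and resetting of
    circadian calcium and clock-gene reporter rhythms in suprachiasmatic
    nucleus (SCN) slice recordings. Provides a synthetic-data generator
    built on temperature-dependent, hierarchically coupled Stuart-Landau
    (Hopf normal form) oscillators observed through a fluorescent-reporter
    model; a rhythm quantification pipeline (dF/F0, 24-h running-average
    detrending, peak detection, period, amplitude, baseline level,
    rhythmicity); circular phase statistics on the 24-h circle (circular
    mean, circular SD, Rayleigh uniformity test, Rayleigh plots); and the
    calcium-probe calibration maths for EGTA-buffered solutions (pH and
    Van't Hoff temperature correction of binding constants, log-log Hill
    linearisation, fluorescent-protein brightness correction and absolute
    calcium estimation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
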