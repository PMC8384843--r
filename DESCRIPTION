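Package: plethysim
Title: Mechanistic Simulation and Analysis of Small-Animal Whole-Body Plethysmography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates an artificial lung model (a servo-driven, heated and
    humidified bulb with interchangeable airway resistances) inside a
    whole-body plethysmography chamber, in both closed (barometric) and
    bias-flow (pneumotach) recording modes, and implements the complete
    recording-analysis chain: zero-phase band-pass filtering, two-point flow
    calibration, flow integration with cycle reset, closed-chamber volume
    calibration, chamber time-constant estimation from occlusion-release
    decays, breath segmentation, tidal volume with the Drorbaugh-Fenn
    temperature/humidity adjustment, enhanced-pause (Penh) waveform metrics,
    and heated-minus-unheated trace decomposition. The simulator makes the
    two overlapping pressure components of the chamber signal (conditioning
    of inspired air versus resistance-driven compression) explicit and
    reproducible, so that the dependence of apparent tidal volume on the
    chamber corner frequency and of Penh on expiratory drive can be studied
    in silico.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
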