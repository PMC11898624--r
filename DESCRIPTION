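Package: stemresp
Title: Stem Respiration Chamber Fluxes, Apparent Respiratory Quotient and
    Respired-Carbon Isotopes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing pipeline for closed-chamber stem gas-exchange
    campaigns: conversion of raw 10-s CO2/O2/humidity sensor logs into stem
    CO2 efflux and O2 influx (ideal-gas closed-chamber flux equation), with
    Magnus-formula humidity conversion, non-trace-gas dilution correction of
    O2, fit-window extraction, regression quality control, gap filling and
    interquartile-range outlier screening of the apparent respiratory
    quotient (ARQ). Also implements Davidson correction of flask delta-13C of
    respired CO2, bomb-radiocarbon mean-age estimation of respired carbon
    against an atmospheric Delta-14C record, two-endmember
    carbohydrate/lipid substrate-mixing inference, and areal quantification
    of Oil-Red-O-stained neutral lipid droplets in wood sections by random
    region-of-interest sampling. A forward simulator of chamber headspace
    dynamics, flask incubations and stained-section images with known ground
    truth supports parameter-recovery validation of every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    png,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml,
    zoo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
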