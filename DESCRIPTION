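Package: nachrscreen
Title: Plate QC, Hit Calling and Selectivity Profiling for Nicotinic
    Receptor Antagonist Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for high-throughput membrane-potential
    screens against nicotinic acetylcholine receptor (nAChR) subtypes.
    Provides 384-well plate layouts with edge-well exclusion and in-plate
    controls, plate-level quality control (control CV, signal-to-background
    ratio, Z'-factor, positional-bias diagnostics), control-anchored
    normalization to a normalized fluorescent signal (NFS), hit calling by
    the mean minus three standard deviations rule with duplicate-run
    confirmation, four-parameter logistic concentration-response fitting
    (EC50/IC50, EC90 derivation), orthogonal rubidium-efflux validation,
    and cross-subtype selectivity classification. A seeded synthetic-data
    generator emulates complete duplicate-run screens with known planted
    ground truth for end-to-end verification.
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
    minpack.lm,
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
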