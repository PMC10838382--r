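Package: effluxr
Title: Dose-Response, Bliss Synergy, Caco-2 Transport and Expression-Screen
    Analysis for Efflux-Mediated Drug Resistance Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for in vitro studies of transporter-mediated
    (P-glycoprotein/ABCB1) drug resistance and its pharmacological reversal:
    four-parameter logistic concentration-response fitting with relative IC50
    and censoring conventions, relative-resistance ratios, checkerboard Bliss
    independence synergy scoring and classification, bidirectional Caco-2
    transwell permeability (Papp, efflux ratio, recovery) with substrate and
    inhibition calls, and RNA-seq style count-matrix quality control (sum of
    Euclidean distances, Hoeffding's D, mean Pearson correlation,
    Kolmogorov-Smirnov statistic) with a fold-change/FDR differential
    expression filter. Ships seeded mechanistic simulators for viability
    plates, transwell assays and count matrices that carry their ground truth,
    so every stage is testable end to end.
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
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
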