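Package: gridvar
Title: Within-Module Variability of Grid-Cell Properties and Single-Module
    Position Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying heterogeneity of grid-cell firing
    properties within a single grid module and for measuring its effect on
    the encoding of position. Builds occupancy-normalized rate maps and
    spatial autocorrelograms from foraging trajectories and spike trains,
    fits grid spacing, orientation and grid score with hexagonal-structure
    inclusion criteria, estimates within-cell versus between-cell
    variability of spacing and orientation by split-half resampling, and
    evaluates cross-validated linear template decoding of position from
    synthetic and recorded single-module grid-cell populations. Includes a
    controlled generator of synthetic grid-cell recordings (ideal
    three-plane-wave rate maps, Poisson spiking, smooth foraging
    trajectories) with known ground-truth parameters.
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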