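Package: reefspc
Title: Processing and Design-Based Estimation for Stationary Point Count Reef Fish Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for working with observation-level stationary point count
    (SPC) reef fish survey data as collected by large-scale Pacific coral reef
    monitoring programs. Reads and validates the published comma-separated
    observation dialect, converts counts and estimated lengths into abundance
    and biomass densities via allometric length-weight relationships, collapses
    paired diver cylinders into site-level sample units, and pools sites to
    stratum and island scale with design-based area weighting. Includes
    Neyman-style survey-effort allocation, observer quality-control
    diagnostics (paired diver differences, size-calibration trials, species
    identification test scoring), structural-complexity summaries, and a
    synthetic survey generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
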