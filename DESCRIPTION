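Package: faceshift
Title: Markerless Video-Based Staging of Unilateral Peripheral Facial Palsy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Objective staging of unilateral peripheral facial palsy from
    68-point facial-landmark trajectories. Converts per-frame landmark
    coordinates into per-side feature distances (eyebrow to upper eyelid for
    forehead frowning, mouth corner to mouth centre for smiling), measures each
    side's movement shift as the maximum excursion minus the mean distance at
    rest, derives shift differences and asymmetry indices between the healthy
    and the affected hemiface, and assigns House-Brackmann grades II-V from
    calibrated per-feature range tables. Includes a synthetic landmark-track
    simulator with ground truth, cohort summary statistics with one-way ANOVA
    effect sizes, CSV/JSON interchange formats, a pluggable landmark-detector
    adapter, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
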