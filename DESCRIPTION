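Package: soniscape
Title: Multi-Timescale Soundscape Appraisal and Sonic-Climate Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated appraisal of environmental soundscapes. Converts audio
    recordings into a cochleogram-style time-frequency representation,
    separates it into four perceptual layers by cascaded slow-envelope
    subtraction at second, minute and hour time scales, maps per-second layer
    audibility onto the pleasantness-eventfulness circumplex (ISO 12913
    quadrants), aggregates appraisals into sonic-climate histograms, and
    computes local signal-to-noise audibility exceedance curves for annoyance
    assessment. Includes a seeded synthetic acoustic-scene generator with
    ground-truth layer and quadrant labels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
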