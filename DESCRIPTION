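Package: phenoring
Title: Radial Layouts for Near-Surface Phenology Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Encodes cyclical, multidimensional near-surface phenology time
    series as radial layouts of concentric rings and angular segments. Reads
    and validates phenology CSV tables (year/month/doy plus named variables),
    computes green/red/blue chromatic coordinate indices from RGB phenocam
    frames over polygonal regions of interest, aggregates daily series to
    weekly or monthly timescales, builds resolution-independent radial scenes
    (one ring per variable or per year, angular segments per time bin), and
    renders them to PDF or PNG. Includes a deterministic synthetic-data
    generator (double-logistic seasonal greenness curves, ground-observation
    series, and matching synthetic camera frames) and a batch command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    jsonlite,
    png,
    yaml,
    grDevices,
    graphics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    withr,
    EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
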