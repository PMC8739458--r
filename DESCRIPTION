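Package: lcmsqc
Title: Quality-Control Toolkit for Targeted LC-MS/MS Batch Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Parses targeted-quantification batch XML exports from liquid
    chromatography tandem mass spectrometry (LC-MS/MS) assays into a
    three-table relational model (batch, calibration, results), evaluates
    per-sample quality-control rules (relative retention time, internal
    standard peak area, first-calibrator signal, signal-to-noise, ion
    ratio), re-derives cutoffs from historical distributions by percentile
    exclusion, compares rule sets by flag deltas, and computes the data
    behind instrument-performance dashboard views. Ships a synthetic batch
    generator so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    DBI,
    RSQLite,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang (>= 1.0.0),
    stats,
    tibble,
    tidyr,
    withr,
    xml2,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
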