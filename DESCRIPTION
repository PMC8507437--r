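Package: lakecal
Title: Cross-Sensor Alignment of Lake Chlorophyll-a and Turbidity Retrievals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aligns water-quality retrievals from a high-resolution satellite
    sensor (MSI-like) to a medium-resolution reference ocean-colour sensor
    (OLCI-like) over inland waters. Implements band-ratio and semi-analytical
    chlorophyll-a algorithms (OC2, OC3, NIR-red ratio, Gons05) and the Nechad
    single-band turbidity algorithm; a seven-step matchup filtering cascade
    with per-algorithm range gates; coefficient tuning by equal-lake-weight
    bootstrap robust nonlinear least squares with a Cauchy loss; linear
    band-ratio and turbidity scaling alternatives; agreement statistics
    (MAD, MAPD, RMSD, Pearson R, bias, residual percentiles), Welch's t-test,
    residual-versus-distance-to-land summaries and optical-water-type
    stratification by spectral-angle classification; and a synthetic
    paired-sensor matchup generator so the full pipeline is testable without
    satellite archives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
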