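Package: standwater
Title: Tree, Stand and Regional Water Use from Heat-Pulse Sap Flow and
    Eddy Covariance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates water use by invasive tree stands from raw field
    measurements. Converts heat-ratio-method (HRM) heat-pulse logger
    records to sap velocity, wound-corrected sap flux and whole-tree
    water use via a sapwood-area allometry; aggregates to daily, seasonal
    and habitat summaries and to stand transpiration through stem size
    classes. Processes eddy-covariance records (despiking, double
    rotation, lag correction, density/WPL adjustment) into sensible and
    latent heat fluxes and actual evapotranspiration, computes FAO-56
    Penman-Monteith reference evapotranspiration and the crop coefficient
    as the origin-constrained slope of ETa on ETo, and regresses water
    use on micrometeorological drivers. Upscales stand water use over a
    fractional-cover raster to regional daily and annual volumes and
    values the water via basin tariffs and irrigated-crop equivalents.
    Includes a synthetic-data generator with known ground truth for every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    zoo,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
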