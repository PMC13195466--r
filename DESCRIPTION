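Package: pfsmoke
Title: Prescribed-Fire Contributions to PM2.5 and Its Chemical Components
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A multistage pipeline for estimating prescribed-fire (PF)
    contributions to ambient fine particulate matter (PM2.5) and its chemical
    components (elemental carbon, organic carbon, nitrate, sulfate).  Stages
    include calibration of satellite-detected burned area against state burn
    permit records, a generic fuel-consumption emissions model, zero-out
    source attribution by differencing paired with/without-PF concentration
    fields, observation-model data fusion with mass-balance-preserving
    species-to-total ratio adjustment, cross-validated model performance
    evaluation, and area-weighted zonal and seasonal aggregation with
    exceedance statistics.  A synthetic-study generator produces paired
    gridded fields, degraded fire records, and monitor observations with
    known ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
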