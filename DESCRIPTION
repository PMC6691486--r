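Package: thermalscape
Title: Microclimate and Physiological Performance Mapping over Complex Terrain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps the thermal and physiological landscape of topographically
    complex sites such as rocky intertidal shores. From a fine-scale digital
    elevation model and hourly weather and tide forcing, the package derives
    per-cell terrain properties (slope, aspect, horizon angles, sky view
    factor), downscales global solar irradiance to per-cell incident shortwave
    flux (direct/diffuse partitioning, cast shadows, terrain reflection),
    solves a steady-state surface heat budget for hourly surface temperature
    with emersion/immersion masking, converts temperature to organismal
    relative performance through thermal performance curves, and summarises
    the resulting fields with roughness (Rq, RqT, RqP), micro-refugia,
    thermal-corridor and two-species interaction metrics. Synthetic terrain,
    weather and tide generators make every stage testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
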