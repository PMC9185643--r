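Package: agrisurvey
Title: UAV Survey Route Planning and Multispectral Vegetation Index Processing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plans UAV photogrammetric survey missions over field polygons and
    processes the multispectral imagery they produce. Route planning converts a
    WGS-84 field polygon, a camera model and a target ground sampling distance
    into an optimized zigzag waypoint mission: flight altitude from the pinhole
    model, footprint tessellation with a modified ray-casting inclusion rule,
    battery-safe go-home sub-routes, and export to mission JSON or QGC WPL 110
    text compatible with Mission Planner. Image processing covers multiband
    cube I/O (ENVI and TIFF), empirical-line reflectance calibration against
    gray-scale reference panels, a declarative registry of 18 vegetation
    indices (NDVI, SAVI, MCARI, ...), threshold classification, histograms,
    pseudo-color rendering and PDF reports. A deterministic synthetic-scene
    generator makes every stage testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    png,
    tiff,
    stats,
    grDevices,
    graphics,
    utils,
    tools
Suggests:
    geosphere,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
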