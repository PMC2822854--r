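Package: shelfbreak
Title: Behavioural Classification and Shelf-Break Habitat Association for
    GPS-Tracked Seabirds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for GPS biotelemetry of pelagic seabirds
    combining high-resolution (5-second) and duty-cycled (burst every two
    hours) tracks. Fits a Gaussian mixture to log-transformed over-ground
    speeds by expectation-maximisation to separate drifting from flight,
    transfers the model to sparse burst tracks, tests the association
    between behaviour-classified locations and seafloor depth with a
    rotation-based randomisation null and repeated two-sample
    Kolmogorov-Smirnov tests, and profiles path unpredictability with a
    windowed entropy measure. Includes generators for synthetic two-state
    tracks and shelf-break bathymetry so every stage is testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    grDevices,
    stats,
    utils,
    xml2
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
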