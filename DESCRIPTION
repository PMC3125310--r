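Package: mcidss
Title: Spatial Decision Support for Mass-Casualty Evacuation Triage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale spatial decision support for mass-casualty incident
    (MCI) evacuation. Builds an impedance-weighted travel-time model on a
    road network (speed limits, stop-sign and traffic-light delays),
    discretizes segments to a maximum length, precomputes an
    origin-destination table of shortest driving times from every segment
    centroid to every hospital, ranks evacuation destinations by driving
    time, trauma level and capacity, allocates patients greedily within
    trauma-priority tiers, and validates model times against logged
    ambulance trips. Includes a seeded synthetic grid-city generator so
    the whole pipeline is testable without proprietary road data, and a
    command-line interface wiring all stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
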