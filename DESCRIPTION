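Package: aedplace
Title: Risk-Based Siting of Automated External Defibrillators on Walkable
    Road Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A three-stage pipeline for planning public-access automated
    external defibrillator (AED) locations. Candidate sites are road
    intersections characterized by walking-time isochrones on a network;
    a regression tree predicts an ordinal out-of-hospital cardiac arrest
    (OHCA) alert-risk level from demographic and infrastructural features
    of each isochrone; and a greedy maximum-coverage heuristic with
    isochrone-based removal and risk decay prioritizes placements.
    Includes scenario-based coverage evaluation against historical alert
    points, a synthetic city generator with a planted spatial alert
    intensity for end-to-end testing, and GeoJSON/CSV/YAML input-output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    rpart,
    stats,
    utils,
    yaml
Suggests:
    geosphere,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
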