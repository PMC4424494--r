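Package: pigmentnet
Title: Directed Signalling Network Analysis of UV-Mediated Skin Pigmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds compartmentalised directed signalling networks of
    UV-mediated human skin pigmentation from curated interaction tables
    (keratinocyte/melanocyte cross-talk), computes topology metrics
    (degree, betweenness, closeness, radiality, hubs), enumerates shortest
    signalling routes from triggers/receptors to phenotypic end processes,
    and identifies essential nodes by virtual single-node knockout.
    Includes a seeded generator of layered two-compartment networks and
    desk-scale fixtures for all analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
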