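Package: reefresilience
Title: Metapopulation Resilience and Conservation Offsets on Reef Dispersal Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates the recovery (Pimm resilience) of a coral-reef fish
    metapopulation whose sub-populations grow logistically and exchange
    recruits over a distance-decay dispersal network. Provides tools to build
    the thresholded exponential-decay link set from reef coordinates, to
    synthesize realistic elongated reef strips, to run seeded Monte-Carlo
    disturbance experiments measuring recovery time of aggregate biomass,
    to sweep connection quality (s) against connection quantity (alpha), and
    to extract iso-resilience curves and solve linear-budget conservation
    offset problems (cheapest way to restore a target recovery time when the
    number of connections is capped).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    grDevices,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    withr
Config/testthat/edition: 3
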