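Package: espkit
Title: Ecological Security Pattern Construction on Raster Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds and compares ecological security patterns (ESPs) for
    mountainous landscapes on gridded data. Identifies ecological sources by
    morphological spatial pattern analysis (MSPA), by nature-reserve
    importance, and by an integrated strategy filtered through a weighted
    niche-suitability overlay; synthesises a minimum-cumulative-resistance
    surface from classified environmental and anthropogenic factors; extracts
    least-cost ecological corridors between source patches; locates strategic
    and artificial ecological nodes from D8 ridge/valley analysis of the
    resistance surface; scores the resulting corridor network with the alpha,
    beta, gamma and cost-ratio connectivity indices; and profiles sources,
    corridors and nodes across altitudinal bands. Ships a seeded synthetic
    mountain-landscape generator with vertical zonation so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    EBImage,
    mgcv,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
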