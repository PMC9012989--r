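Package: thermoapos
Title: Knowledge Mining of Infrared Thermography with Attribute Partial
    Order Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for mining whole-body infrared thermography (IRT)
    temperature fields: bimodal background filtering on the temperature
    frequency curve, anchor-point based segmentation into 18 regions of
    interest, deterministic one-dimensional K-means granulation of each
    region into binary high/low temperature attributes, assembly of the
    resulting formal context, generation of an attribute partial order
    structure (APOS) knowledge graph, and face-chest temperature-difference
    statistics (Welch and pooled t tests, confidence intervals, power).
    Includes a synthetic thermal-phantom generator so every stage can be
    exercised end to end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    car,
    png,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
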