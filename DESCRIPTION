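Package: mdlink
Title: Record Linkage of Medical-Device Safety Notices to a Device Registry
Version: 0.1.0
Authors@R: person("Open", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Links free-text medical-device safety notices to a national
    device registry for post-market surveillance. Implements a two-phase
    entity-resolution pipeline (TF-IDF cosine blocking of manufacturers,
    then Levenshtein token-set fuzzy matching of device names under an
    iterative 95-to-60 threshold schedule), parsing and level-wise
    comparison of hierarchical EMDN/CND nomenclature codes, linkage-quality
    validation against notices carrying a registry identifier (including a
    mid-P McNemar comparison of matching methods), surveillance
    aggregation by year, nomenclature category and manufacturer, and a
    synthetic registry/notice generator with ground truth so the whole
    pipeline is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
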