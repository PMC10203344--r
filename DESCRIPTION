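Package: pddisc
Title: Pattern Discovery and Disentanglement for Mixed-Mode Tabular Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers statistically significant, source-disentangled
    attribute-value association patterns in discrete or mixed-mode tabular
    data. Builds an adjusted-standardized-residual association matrix over
    all attribute values, disentangles it by principal component analysis
    into per-component association spaces, clusters attribute values into
    statistically connected groups and cover-similarity subgroups, tests
    high-order patterns with a residual hypothesis test and a delta-closed
    filter, clusters entities by shared attribute values, detects and
    corrects mislabelled entities, and assembles an interpretable
    three-space knowledge base (knowledge, pattern and entity spaces).
    Includes a synthetic-data generator with implanted associations and
    label noise for end-to-end validation against known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
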