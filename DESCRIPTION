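Package: tmwas
Title: Targeted Metabolome-Wide Association Scans and Metabolic
    Correlation Networks
Version: 0.2.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Targeted metabolome-wide association analysis for
    high-resolution LC/MS metabolomics feature tables: correlate anchor
    metabolites against every measured m/z feature with Benjamini-Hochberg
    false-discovery-rate control, match and annotate features by ppm mass
    tolerance and adduct/isotope arithmetic, filter features by technical
    quality criteria, compare feature sets across studies, and build full
    or shrinkage partial-correlation association networks around seed
    metabolites at graded stringency, with Manhattan-style plots, GML
    network export for Cytoscape, and a JSON run manifest. Includes a
    synthetic feature-table generator with planted correlation structure
    so every step can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    igraph,
    jsonlite,
    MASS,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
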