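Package: replicyte
Title: Quantitative Analysis of Nucleoside-Analogue DNA Replication Labelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying DNA-replication labelling experiments
    (BrdU/EdU immunofluorescence) from two-channel microscopy images and
    flow-style event tables. Provides nucleus segmentation from the DAPI
    channel, per-nucleus intensity measurement, the trimmed-fraction
    signal-to-background ratio statistic (R/non-R ratio) with estimation of
    the labelled fraction, first-order antibody-dissociation kinetics with
    formaldehyde stabilisation modelling, bivariate cell-cycle gating on
    replication signal versus DNA content, and a synthetic-data generator
    that emulates labelled cell populations so the whole pipeline can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    yaml,
    jsonlite,
    ggplot2,
    withr,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
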