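Package: responderomics
Title: Multi-Omics Two-Group Responder Comparison for Targeted Panels and
    Label-Free Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native pipeline for comparing two responder groups
    across a targeted mRNA panel and label-free FFPE proteomics: housekeeping
    geometric-mean normalization with a minimal multiple-of-100,000 scale
    factor, rank-invariant (IRON-style) normalization against a
    correlation-selected median sample, a composite differential filter
    (fold change, Welch t-test, Hellinger distance), Fisher's exact gene-set
    enrichment against a pruned observed-gene universe, and seed-node
    direct-interaction subnetwork extraction. Ships a synthetic-data
    generator emulating the assay designs so the full pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
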