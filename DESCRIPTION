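Package: notchtrunc
Title: Detection and Quantification of NOTCH1-Class Activating Truncations
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis toolkit for NOTCH1-class activating
    rearrangements in renin-secreting kidney tumours and related neoplasms.
    Provides quality-rule filtering of somatic variant calls, structural
    variant breakpoint-consequence annotation against a strand-aware
    gene/domain model (extracellular, transmembrane and intracellular
    domains, plus disruption of the NRARP negative regulator), per-exon
    coverage normalisation and the intracellular/extracellular domain
    expression ratio, single-nucleus quality control with doublet-cluster
    removal and the endothelial-normalised NOTCH1-target/NRARP ratio
    statistic, and bulk cross-cohort comparison via TMM-normalised log-CPM.
    A synthetic-data module generates every input with known planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    optparse
Config/testthat/edition: 3
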