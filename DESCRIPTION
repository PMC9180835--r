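Package: memomiR
Title: Drought Memory-Related miRNA Discovery from Small RNA and Degradome Sequencing
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies stress (drought) memory-related microRNAs from UMI-labelled
    small RNA sequencing and validates their targets with degradome (PARE) data.
    Implements adapter trimming with UMI extraction and PCR-duplicate removal,
    contaminant filtering, ACGT101-style miRNA classification (known, conserved and
    novel groups) with Nussinov hairpin prediction and variant naming, per-million
    normalization with t-test/ANOVA differential expression, the memory-candidate
    set logic over primed (DM), direct-drought (DD) and control (CG) contrasts,
    degradome T-plot categorization with plant miRNA-target duplex scoring, and
    hypergeometric GO/KEGG over-representation of validated targets. A synthetic
    scenario generator emulates the three-group by four-timepoint study design so
    the whole chain can be exercised and tested without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
biocViews: Sequencing, SmallRNA, GeneExpression, DifferentialExpression
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
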