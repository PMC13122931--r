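Package: cfEntropy
Title: Fragment-Level Methylation Entropy and Multimodal cfDNA Cancer Detection
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for multi-cancer early detection from targeted bisulfite
    sequencing of cell-free DNA. Implements fragment-level methylation entropy
    (BiEntropy of per-read CpG patterns averaged over MethBin regions),
    U-reads abundance (URA), DELFI-style fragment-length coverage profiles,
    a threshold/random-forest/Boruta feature-selection cascade, binary
    (cancer vs non-cancer) and tissue-of-origin classifiers with late fusion,
    and a stage-interception simulator for screening benefit. Includes a
    fully synthetic bisulfite cohort generator so every stage is testable
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    glmnet,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Epigenetics, DNAMethylation, Classification, Sequencing
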