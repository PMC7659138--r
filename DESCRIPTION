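Package: LinkedReadTools
Title: Simulation and Profiling of Linked-Read Metagenome Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how linked-read (10x-style barcoded)
    sequencing parameters shape metagenome assembly. Simulates barcoded
    paired-end reads from microbial communities with uneven abundance under
    a four-parameter model (fragment physical depth C_F, per-fragment read
    depth C_R, mean fragment length mu_FL, fragments per partition N_F/P),
    reconstructs long DNA fragments from co-barcoded alignment coordinates
    by greedy extension, estimates the parameter vector from fragment sets,
    implements read- and barcode-level subsampling, and classifies assembly
    bins into draft-genome quality tiers with an abundance statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
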