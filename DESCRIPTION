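Package: SyngenMarkers
Title: Molecular Typing of the Paramecium bursaria Syngen Complex
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery of clade-diagnostic synapomorphies in aligned rDNA
    (SSU, ITS) and translated mitochondrial (COI) markers of the Paramecium
    bursaria species complex, signature-based assignment of sequences to the
    five syngens R1-R5, statistical-parsimony (TCS) haplotype networks
    annotated with geographic composition, distance-tree monophyly checks,
    and a truth-tracked synthetic data generator so that every stage of the
    workflow is testable without sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Phylogenetics, Classification, Alignment, Software
RoxygenNote: 7.3.3
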