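Package: SialoKit
Title: Sialotranscriptome Assembly, Coding-Sequence Extraction and
    Salivary Protein Family Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing deep pyrosequencing surveys of
    blood-feeding arthropod salivary gland transcriptomes (sialomes).
    Implements iterative word-size-scheduled read clusterization with
    greedy quality-weighted consensus assembly, frameshift-repairing
    coding-sequence extraction from translated homology alignments,
    multi-evidence functional classification into secreted,
    housekeeping, unknown and transposable-element classes, progressive
    identity-threshold protein family clustering with gene-count
    estimation, PROSITE-style motif scanning, and neighbor-joining
    bootstrap clade analysis.  A synthetic 454-style read generator with
    full ground-truth bookkeeping makes every stage testable end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
biocViews: Transcriptomics, SequenceMatching, Alignment, Phylogenetics
RoxygenNote: 7.3.3
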