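Package: subgenomics
Title: Subgenome Evolution and Homoeolog Expression Analysis for
    Allopolyploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying whole-genome duplication (WGD) and
    subgenome evolution in allopolyploid plants. Implements codon-level
    evolutionary statistics (NG86-style Ka/Ks with equal-weight pathway
    averaging, fourfold-degenerate-site transversion rates), collinear
    synteny-block detection by dynamic-programming chaining, Ks-peak
    detection and molecular dating of duplication and speciation events,
    outgroup-guided assignment of pseudochromosomes to parental
    subgenomes, homoeolog expression bias and dominance classification,
    differential-expression thresholding, WGD-paralog expression
    divergence classes, and hypergeometric set enrichment. A seeded
    synthetic allotetraploid generator provides ground truth (sequences,
    collinear gene orders, expression with planted effects) for every
    stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    jsonlite,
    S4Vectors,
    rtracklayer,
    GenomicRanges,
    BiocGenerics,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
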