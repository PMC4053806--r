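Package: graphrbp
Title: Graph-Kernel Models of RNA-Binding Protein Binding Preferences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Learns RNA-binding protein (RBP) binding preferences from
    CLIP-seq derived binding sites or in vitro affinity measurements.
    Candidate sites are extended by folding context, secondary structure
    is sampled as shape-representative structures (shreps) over sliding
    windows, and sequence plus structure are encoded as directed,
    annotated hypergraphs. Explicit neighborhood-subgraph-pairwise-distance
    (NSPD) kernel features restricted to a binding-site viewpoint feed a
    margin-based classifier (stochastic gradient descent) or an
    epsilon-insensitive support vector regression. Fitted models yield
    prediction margins, per-nucleotide binding profiles, high-affinity
    site calls, and sequence/structure motif matrices for logos.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    Matrix,
    kernlab
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
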