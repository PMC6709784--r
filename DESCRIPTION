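Package: pannlrome
Title: Construction and Characterization of a Species-Wide Pan-NLRome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and characterizes a species-wide pan-NLRome: the
    complement of nucleotide-binding leucine-rich-repeat (NLR) immune
    receptor genes across a panel of accessions. From per-accession gene
    models, protein/CDS sequences and protein-domain interval tables, the
    package identifies NLRs and assigns classes (TNL/CNL/RNL/NL) and
    collapsed domain architectures, clusters proteins into orthogroups via
    ortholog/inparalog edge typing and Markov clustering, refines
    orthogroups by outlier removal, distance trees and paralog-aware
    pruning or splitting, classifies orthogroups into core/shell/cloud,
    computes per-orthogroup and per-domain diversity and neutrality
    statistics (pi, Watterson's theta, Tajima's D, Fu and Li's D* and F*,
    Ramos-Onsins and Rozas' R2, Strobeck's S), runs bootstrap rarefaction
    of orthogroup and diversity discovery, anchors non-reference
    orthogroups through contig co-occurrence networks, and scores assembly
    quality and completeness. A seeded coalescent-based simulator
    generates ground-truthed synthetic pan-NLRomes so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    Rcpp,
    ape,
    phangorn,
    igraph,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
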