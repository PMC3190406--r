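Package: traitnet
Title: Heterogeneous Complex-Trait Networks: Assembly, Projection and
    Propagation-Based Gene Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds five-layer heterogeneous networks for human complex
    traits from tabular GWAS association records, protein-protein and
    protein-DNA (transcription-factor binding site derived) interactions,
    disease-tissue, tissue-gene and drug-gene relationships. Disease-gene
    edges are weighted by -log10 of the association p-value, with Fisher
    meta-analysis of replicated phenotype-SNP reports and user-selectable
    significance thresholds and degrees-of-separation neighbourhood
    expansion. Provides bipartite similarity projection (e.g. diseases
    connected by shared genes), candidate-gene prioritization by random
    walk with restarts on the gene-gene layer and by a PRINCE-style
    network-propagation algorithm extended to the full heterogeneous
    network with a GWAS-derived disease-similarity prior, a deterministic
    synthetic-fixture generator with planted disease modules for
    benchmarking, and readers/writers for TSV, SIF and GraphML exchange.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml,
    methods,
    stats,
    utils,
    graphics,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
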