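Package: crypticsplice
Title: Differential Splicing and Cryptic Exon Analysis for TDP-43 Proteinopathies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tidy pipeline for cluster-level differential splicing analysis
    of bulk brain RNA-seq junction counts, aimed at detecting cryptic splicing
    driven by TDP-43 loss of function. Splice junctions are clustered by shared
    splice sites and tested with a Dirichlet-multinomial generalized linear
    model (likelihood-ratio tests with Benjamini-Hochberg correction), with
    optional adjustment for estimated brain cell-type composition via
    marker-based deconvolution and proportion principal components. Junctions
    are annotated against a reference transcriptome to flag novel donors,
    acceptors and donor-acceptor pairs, classify event types (exon inclusion,
    exon skipping, alternative splice sites) and cassette-exon directionality,
    and select cryptic events. Cryptic transcripts are reconstructed from the
    genome, translated in silico, and classified by predicted protein
    consequence and structural category. Cross-study splice-event matching
    harmonizes cryptic event lists across published datasets. A synthetic-data
    generator emulates the junction-count, annotation and cell-mixture
    structure of such studies for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    igraph,
    stats,
    utils,
    tools,
    methods,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
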