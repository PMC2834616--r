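Package: fflnet
Title: miRNA-TF Feed-Forward Loop Discovery and Regulatory Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds combinatorial microRNA-transcription factor regulatory
    networks from annotation-style inputs: promoter assignment for genes,
    miRNA precursors and miRNA clusters; Z-score and conservation filtered
    mapping of transcription factor binding sites; enumeration of
    TF-miRNA-gene feed-forward loops and miRNA-TF mutual feedback loops;
    network convergence with core-node (hub) detection; Fisher and
    permutation enrichment tests; and annotation of SNPs falling on
    regulatory elements. Includes a synthetic-data generator with planted
    loop structure so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    igraph,
    yaml,
    generics,
    IRanges,
    S4Vectors,
    stats,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
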