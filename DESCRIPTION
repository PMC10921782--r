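Package: panquant
Title: Reference Bias in Polyploid RNA-Seq Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and measurement of reference bias in RNA-seq
    quantification of allopolyploids such as bread wheat. Provides a
    miniature allohexaploid pangenome simulator with controlled
    orthologue divergence and introgression blocks, an error-free
    paired-end read simulator, a k-mer equivalence-class pseudoaligner
    with even count splitting, pantranscriptome reference construction
    with one-to-one orthologue count aggregation, gene-level bias
    classification and windowed bias scores, homoeologue triad balance
    classification, and detection of divergent or deleted genomic
    regions from windowed mapping-coverage deviation with robust (MAD)
    outlier flagging.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
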