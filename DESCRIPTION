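Package: circjunct
Title: Statistically Based Detection of Circular RNA Splice Junctions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects circular RNA backsplice junctions from RNA-seq read
    alignments using a statistically based framework: construction of linear
    and scrambled exon-exon junction reference databases from a genome and
    annotation, classification of read pairs into linear, circular and decoy
    categories, a two-step weighted logistic GLM that converts per-read
    alignment features into per-junction posterior probabilities with p-values
    and false discovery rates, consensus-scored de novo junction discovery
    with splice-signal annotation, and downstream statistics for developmental
    induction of circular relative to linear isoforms. Includes a full
    synthetic-data generator (toy genomes, paired-end reads with a per-base
    error model and homology-driven decoys, feature tables, and
    multi-timepoint count tables) so the whole pipeline runs without an
    external aligner or downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    rtracklayer,
    Rsamtools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
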