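Package: igsim
Title: Intergenomic Similarity Calculation and Clustering for Viral Genomes
Version: 0.1.0
Authors@R: person("igsim", "developers", role = c("aut", "cre"),
    email = "igsim@example.org")
Description: Computes pairwise intergenomic similarities and distances
    between viral genomes from all-vs-all BLASTN local alignments, following
    the traditional ICTV Bacterial and Archaeal Viruses Subcommittee
    approach. Overlapping alignments are de-replicated so that every genome
    region is counted once, and identical-base counts are normalized to the
    sum of both genome lengths. Includes alignment-quality indicators
    (aligned fractions, genome length ratio), hierarchical clustering with
    species/genus demarcation thresholds, an ordered similarity/distance
    matrix, a composite heatmap, and cluster tables, plus a synthetic-genome
    fixture generator for testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    ComplexHeatmap,
    circlize,
    grDevices,
    grid,
    methods,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
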