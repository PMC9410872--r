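Package: ampliconpanel
Title: Genome-Wide Marker Design and Target Amplicon Sequencing Genotyping
    for Heterozygous Outcrossing Crops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A workflow for designing multiplex amplicon-sequencing marker
    panels in highly heterozygous, large-genome outcrossing crops such as
    onion, and for genotyping F2 populations with them. Starting from
    per-individual transcriptome variant tables of two parental lines, the
    package detects inter-line polymorphic sites under within-line consensus
    rules, projects their transcript positions onto genome scaffolds through
    best-hit alignments, designs repeat-masked target-specific primer pairs
    producing short amplicons over each site, selects a panel covering the
    genome and partitions it into multiplex pools. Downstream, it calls
    genotypes from per-sample allele depths at amplicon hotspots, classifies
    markers by parental behaviour, builds A/H/B-coded F2 genotype matrices
    with missing-data and segregation-distortion filters, and performs
    two-point linkage QC (EM recombination fractions, LOD grouping, Haldane
    distances). A seed-deterministic simulator generates every input the
    pipeline consumes, including the reference pair, incompletely fixed
    parental lines, F2 meioses and overdispersed amplicon read depths.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
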