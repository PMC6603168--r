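Package: igflow
Title: UMI-Based B-Cell Receptor Repertoire Analysis from Paired-End Amplicons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for enriching and analysing antigen-experienced
    memory B-cell antibody repertoires from paired-end immunoglobulin amplicon
    sequencing. Implements UMI-based read preprocessing (quality filtering,
    primer/UMI annotation, per-UMI consensus, paired-end assembly, isotype
    annotation, duplicate collapsing), germline V(D)J gene assignment with
    framework/CDR partitioning and somatic hypermutation quantification,
    clonal family inference via distance-to-nearest threshold estimation and
    single-linkage clustering, repertoire summary statistics (isotype and
    V-gene usage, SHM summaries, repertoire dissimilarity index),
    cross-timepoint persistent-sequence detection, monoclonal-antibody-to-
    repertoire clonal matching, parsimony lineage reconstruction, and
    immunodominance ranking. Ships a ground-truth repertoire simulator that
    emulates naive (PBMC) and stimulated/memory B-cell compartments for
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    igraph,
    jsonlite,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    yaml
Suggests:
    ape,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
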