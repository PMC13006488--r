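Package: magdb
Title: Local Relational Database Integration for Metagenome-Assembled
    Genome Workflows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Parses the heterogeneous file outputs of a prokaryotic
    metagenome-assembled genome (MAG) workflow -- genome bin FASTA files,
    Prokka-style GFF3 and protein FASTA annotations, GTDB-Tk taxonomy
    summaries, dRep dereplication tables, CheckM2 quality reports and
    protein-annotation outputs (dbCAN, InterProScan, CLEAN, ProteInfer) --
    into a normalized 28-table relational database held in an embedded
    SQLite file. Biological entities (genomes, contigs, genes, proteins,
    taxa, annotations) are assembled across files via foreign keys, with
    validation, uniqueness constraints, memoized batch insertion and
    referential-integrity auditing. Ships named biological queries (for
    example carbohydrate-active enzymes restricted to taxonomically novel
    MAGs), a read-only HTTP/JSON API, a plugin contract for annotation
    parsers, and a seeded synthetic-project generator with a ground-truth
    manifest for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    DBI,
    RSQLite,
    digest,
    dplyr,
    generics,
    ggplot2,
    httpuv,
    jsonlite,
    purrr,
    RcppTOML,
    readr,
    rlang,
    tibble
Suggests:
    Biostrings,
    curl,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
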