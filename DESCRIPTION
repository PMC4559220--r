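Package: hmcaller
Title: Single-Base 5-Hydroxymethylcytosine Calling and Genomic
    Characterization from Restriction-Digest Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calls single-base 5-hydroxymethylcytosine (5hmC) sites from
    aligned AbaSI restriction-digest sequencing reads using the expected
    cut-site offset from the modified cytosine, builds multi-individual
    consensus site sets with stringency tiers, quantifies between-sample
    overlap with a log-space hypergeometric tail test, computes CG- and
    length-corrected 5hmC densities over chromosomes and annotated
    features, produces peak-centered, metagene and exon-boundary binned
    signal profiles, detects 5hmC clusters with gene assignment and
    gene-set enrichment, and compares sex-specific sites and X-inactivation
    escape. Includes a seeded synthetic-data generator (toy genomes,
    planted multi-individual truth sets, AbaSI-style aligned reads,
    annotation fixtures) so the whole pipeline runs end-to-end without
    external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
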