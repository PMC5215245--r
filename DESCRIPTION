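Package: ampliconbench
Title: Ground-Truthed Benchmarking of Targeted-Metagenomics Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained evaluation toolkit for 16S rDNA amplicon
    (targeted metagenomics) analysis pipelines. Simulates ground-truthed
    amplicon sequencing datasets of controlled community complexity,
    throughput and Ion Torrent-style error profile (in-silico PCR with
    degenerate primers, deterministic read allocation, per-base
    indel/substitution error model with 3'-weighted placement); scores any
    pipeline's read-level taxonomic assignments against the truth with
    rank-specific precision/recall/F-measure, Chao1 richness and its signed
    error percent, Shannon and Inverse Simpson diversity, and
    information-theoretic partition agreement (NMI, AMI, 1-NID); and
    compares abundance profiles across pipelines by UPGMA clustering,
    Bray-Curtis distances, principal coordinates analysis and rank-sum
    tests. A fixture generator produces synthetic marker-bearing genomes
    and a toy taxonomy so the whole protocol runs with no downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    methods,
    stats,
    tools,
    utils,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
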