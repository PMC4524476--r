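Package: adratio
Title: Coverage-Based Assignment of Genome Scaffolds to Sex Chromosomes and Autosomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Assigns anonymous genome assembly scaffolds to the Y chromosome,
    the X chromosome, or the autosomes from the per-position sequencing depth
    of one male and one female individual mapped to a male-derived reference.
    Implements the average-depth (AD) ratio statistic with its masking,
    depth-cap and length filters, threshold-based classification and binned
    histogram summaries; filtering of tabular similarity-search hits with a
    global-alignment identity confirmation step; strict column filters for
    multiple sequence alignments ahead of phylogenetic analysis; coverage
    summaries of repeat annotations; and a seeded simulator that generates
    truth-labelled depth tables, references, hit tables and alignments for
    validating every stage. A command-line entry point exposes each stage as
    a subcommand.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
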