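Package: haloscreen
Title: Halogen-Metabolism Gene Screening for Metagenomes and MAGs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Screens gene annotation tables from metagenomes and
    metagenome-assembled genomes (MAGs) against a curated catalog of
    halogen-metabolism enzyme functions (complete EC numbers covering
    halogenases, dehalogenases and auxiliary pathway enzymes, grouped into
    degradative and biosynthetic clusters). Computes gene densities
    (genes/Mbp) per function and per cluster, cross-sample shared-function
    comparisons, MAG quality tiers from completeness/contamination, GTDB
    taxonomy parsing with taxonomic-novelty calls, taxon-aggregated density
    summaries, and iTOL-ready phylogenetic tree annotation datasets. Includes
    a synthetic-data generator with planted gene densities and ground truth
    for end-to-end validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    ape,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
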