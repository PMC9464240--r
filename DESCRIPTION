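Package: gage
Title: Genome Analysis and Genome Editing for CRISPR/Cas12a Plant Species Identification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: In-silico workflow for CRISPR/Cas12a-based plant species
    identification. Enumerates PAM-bearing 25-mer candidate targets genome-wide
    with copy numbers and density statistics, classifies targets by genome
    annotation, extracts targets restricted to barcode regions such as ITS2,
    screens candidates for species specificity by mismatch-tolerant search
    against adulterant genomes, assembles crRNAs (direct repeat + spacer), and
    calls detection and limit of detection from replicate fluorescence time
    series. Includes a seeded synthetic-data generator (genomes, annotations,
    planted target sites, assay curves) so the whole pipeline is testable
    without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringi,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
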