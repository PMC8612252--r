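Package: heliocontext
Title: Genomic Context Inference for Heliorhodopsins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the function and taxonomic distribution of heliorhodopsins
    (HeRs) and other microbial rhodopsins from annotated genomes and
    metagenomic contigs. Screens candidate proteins by transmembrane topology
    and helix-7 motifs (SxxxK for heliorhodopsins, DxxxK for type-1
    rhodopsins), classifies genomes as diderm or monoderm-consistent by
    counting outer-envelope marker domains, assigns contig taxonomy by
    best-hit voting, detects cotranscription (operon) candidates from
    intergenic distance and strand, tests protein domains for
    overrepresentation in HeR gene neighborhoods with hypergeometric tests
    under Benjamini-Hochberg false-discovery-rate control, and scans for
    fusion-diagnostic motifs (MORN repeats, zinc ribbons) and long
    terminal or loop extensions. Ships a seeded synthetic-genome generator
    with planted ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    withr,
    yaml,
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
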