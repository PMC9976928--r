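Package: tirscape
Title: Discovery, Classification and Integration-Site Analysis of TIR DNA Transposons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for cut-and-paste DNA transposon families
    with short terminal inverted repeats (TIRs) and TA target-site
    duplications (TSDs), modelled on the pogo-superfamily Passer (PS)
    elements. Turns homology hits on a genome into candidate loci, refines
    element boundaries by joint TIR/TSD scoring, classifies copies as
    intact, transposase-coding or fragment using ORF, DNA-binding-motif and
    DD35D catalytic-triad rules, builds family consensus sequences, computes
    Kimura two-parameter divergence and coverage-vs-divergence landscapes,
    and analyses integration-site preference (feature categories, TSS
    profiles, gene-body deciles, expression octiles, chromatin-state
    enrichment and palindromic target-site consensus) against random-locus
    backgrounds with Fisher's exact tests. A synthetic-data module plants
    ground-truthed transposon families and biased insertion sets so every
    stage is verifiable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
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
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
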