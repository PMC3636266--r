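Package: satchrom
Title: Linker Histone ChIP-Seq Occupancy and Satellite Chromatin Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for linker histone (H1) ChIP-seq occupancy and
    pericentromeric satellite chromatin. Builds per-10-million-read normalized
    windowed coverage and IP-IN difference tracks, profiles signal around
    transcription start and termination sites stratified by expression or
    histone-mark level, computes genome-wide Pearson correlations between
    tracks, calls SICER-style enrichment islands with gap-size optimization,
    assigns reads to a repeat consensus library by seeded mismatch matching
    with random multiread placement to quantify repeat-class enrichment, and
    estimates nucleosome repeat length from micrococcal nuclease digestion
    ladders by regression-extrapolation. Ships a synthetic-data generator
    (mini-genomes with tandem satellite arrays, ChIP/input read libraries with
    known enrichment structure, MNase ladders) so the full pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
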