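Package: rhythm24
Title: Fourier-Based Detection of 24-Hour Rhythmicity in Diurnal
    Transcriptome Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects and visualises diurnal (24-hour) rhythmicity in
    transcript-level expression time series using the relative power of
    the 24-hour discrete Fourier period (RP24), permutation significance
    with Benjamini-Hochberg correction, Fourier phase estimation, and
    classification of transcripts into early, robust and late life
    cyclers across two conditions (e.g. young versus old animals).
    Includes a spike-profile ("staccato") screen based on spectral
    parity and the phase variance of even Fourier coefficients,
    circular-phase and dot-and-arrow polar visualisations, promoter
    motif-enrichment statistics, and a synthetic-profile simulator so
    the full pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
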