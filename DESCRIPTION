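Package: enhancer4C
Title: Enhancer Identification from 4C-seq Viewpoint Data with CNV Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for identifying gene enhancers from
    circularized chromosome conformation capture sequencing (4C-seq) viewpoint
    data and screening them for copy-number variants. Covers in-silico
    restriction digestion and unique fragment-end mapping, read demultiplexing
    and fragment-end quantification, contact-peak calling against a monotone
    distance-decay background, putative-enhancer delineation by open-chromatin
    and H3K27ac overlap, TAD assignment, reciprocal-viewpoint confirmation,
    dual-luciferase activity scoring, SNP-array CNV calling with breakpoint
    delimitation, and relative expression by the delta-delta-Ct method.
    Includes a synthetic-data generator that emulates the statistical structure
    of 4C viewpoint experiments so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils,
    Biostrings,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
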