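Package: oxbsq
Title: Quantitation of 5-Methylcytosine and 5-Hydroxymethylcytosine from
    Oxidative Bisulfite Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for separating 5-methylcytosine (5mC) from
    5-hydroxymethylcytosine (5hmC) in paired bisulfite (BS) and oxidative
    bisulfite (oxBS) sequencing libraries. Implements per-site and pooled
    BS-minus-oxBS differencing with optional conversion-chemistry
    correction, spike-in based estimation of bisulfite conversion and
    oxidation efficiencies, CpG-island shore/shelf and promoter
    meta-profiles, repeat-element surrogate levels, and a sex-by-age
    two-way ANOVA layer with Student-Newman-Keuls post hoc testing and
    Benjamini-Hochberg correction. A synthetic methylome generator with an
    explicit conversion-chemistry forward model (plus simulators for qPCR
    dilution series, digital PCR partitioning, and ELISA plates) provides
    ground truth for validation, so the full pipeline can be exercised
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    S4Vectors,
    car,
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
    utils
Suggests:
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
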