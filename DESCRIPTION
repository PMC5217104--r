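Package: iseqr
Title: Pooled Double-Barcode Fitness Assays and Genetic Interaction Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of pooled double-barcode sequencing (interaction
    sequencing, "iSeq") fitness assays in yeast. Counts known double
    barcodes from paired-end amplicon reads, estimates per-strain relative
    fitness from serial-transfer frequency trajectories by zero-intercept
    log-linear regression, computes multiplicative-model genetic
    interaction (epistasis) scores with replicate-strain confidence
    intervals, calls environment-dependent interactions with rank-sum
    tests under FDR control, estimates doubling times from plate-reader
    optical density curves by sliding-window regression, and classifies
    variants as inherited or de novo against a strain pedigree. Includes a
    seeded Wright-Fisher-with-selection simulator of the pooled
    serial-transfer experiment with recorded ground truth for every
    estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
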