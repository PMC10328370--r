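Package: suni
Title: Mutagenic Primer Design and Library Quality Control for Nicking
    Saturation Mutagenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs pools of mutagenic primers for nicking saturation
    mutagenesis of protein-coding regions, in two flavours: a
    melting-temperature-optimized design (opt1) and a design that additionally
    enforces a GC-rich 5' terminus and per-codon NNK/NNS degenerate-codon
    choice (SUNi). Includes a nearest-neighbor melting-temperature engine, a
    quality-control pipeline that classifies amplicon sequencing reads against
    the expected single-codon variant set and reports library uniformity
    (LogDiff) and screening efficiency, a primer-feature correlation analysis
    for diagnosing positional mutagenesis bias, and a synthetic read simulator
    with analytic ground truth for end-to-end validation. All user-facing
    functions take and return tidy data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
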