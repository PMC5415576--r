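Package: tfomer
Title: Transcription Factor Repertoire (TFome) Annotation and Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates transcription factor (TF) repertoires from
    InterProScan-style protein domain tables using a curated catalog of
    TF-type DNA-binding domain (DBD) families, groups TF genes into gene
    families around their dominant DBD, detects and resolves dual-specificity
    TFs, fits per-family and whole-TFome power laws of TF count against
    proteome size, classifies gene families as responsive or non-responsive
    to genome growth, detects and corrects single-species expansions, and
    builds lineage-specific TF signatures for taxonomic assignment. Includes
    a seeded synthetic-data generator emulating fungal and metazoan genome
    annotation corpora so every pipeline stage is testable without
    downloading genome annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    knitr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
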