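Package: cladeprimer
Title: Clade-Specific Primer Design and In Silico PCR Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Design and evaluate PCR primers that discriminate a target
    fungal clade from co-amplifying environmental fungi. Finds
    discriminating windows in a labelled multiple sequence alignment,
    derives degenerate consensus primers with thermodynamic and 3'-end
    quality filters (nearest-neighbor melting temperature, 3' G/C runs,
    dimer screening), and evaluates any primer pair against a
    taxonomically labelled sequence database by in silico PCR under
    explicit mismatch, protected-3'-window and amplicon-length rules.
    Includes a deterministic synthetic-data generator with planted
    discriminating windows for end-to-end validation, developed around
    the mycobiont mtSSU barcoding use case.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
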