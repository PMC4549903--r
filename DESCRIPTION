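Package: nucleokey
Title: Key-Position Analysis of Nucleosome Formation Affinity in
    Oligonucleotide Pools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for fixed-length (150 bp) oligonucleotide
    pools with measured nucleosome-formation affinities. Computes
    position-wise dinucleotide ("diad") frequency profiles, affinity-weighted
    diad scores, learns one weight per diad start position with a
    single-layer network under 10-fold cross-validation, selects key
    positions by weight magnitude, classifies sequences from key positions
    only, and reports accuracy, sensitivity, positive predictive value and
    the Matthews correlation coefficient. Includes a seeded synthetic-pool
    generator with planted position-specific diad biases so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
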