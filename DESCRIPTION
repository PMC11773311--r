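Package: looplig
Title: Sequence-Reactivity Profiling of Nonenzymatic RNA Loop-Closing Ligation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of deep-sequencing assays that partition
    randomized 4-nt RNA overhangs between intramolecular loop-closing ligation
    (forming hairpin tetraloops) and competing splinted (nicked-duplex)
    ligation. Provides a ground-truth-labelled synthetic read generator,
    four-product (P1-P4) read demultiplexing and counting, input-library bias
    normalization (per-sequence alpha factors), sequence-selectivity profiling
    (ranking, fold-range, positional composition, information content, IUPAC
    consensus-group classification), exact hypergeometric overlap statistics
    against a biological tetraloop reference with similarity-based
    deduplication, and rank-versus-yield validation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
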