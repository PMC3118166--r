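Package: pyromap
Title: FM-Index Seed-and-Extend Mapping of Pyrosequencing Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Maps long pyrosequencing (454 GS FLX style) reads to a reference
    genome with a Burrows-Wheeler/FM-index backward search, greedy maximal
    exact-match seeding with homopolymer-aware skip rules, coherent multi-seed
    chaining, and banded affine-gap (Gotoh) extension with semi-global read
    ends. Includes a homopolymer-error read simulator with per-run
    substitution/insertion/deletion events and Zipf-distributed gap lengths,
    a truth-based accuracy evaluator, SAM output, index persistence and a
    small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
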