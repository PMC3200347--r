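Package: barcomp
Title: Distance, Monophyly and Character-Based DNA Barcoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing the three main DNA-barcoding
    species-identification paradigms on one barcode reference library:
    Kimura 2-parameter distance analysis (rank-stratified divergence
    summaries, barcoding-gap diagnostics, the 10x-rule threshold and
    species lumping), neighbour-joining tree building with bootstrap
    support and per-taxon monophyly assessment, and character-based
    (CAOS-style) diagnostic barcodes built from characteristic
    attributes.  Includes a Gblocks-style alignment block filter for
    ribosomal loci and a seeded simulator of multi-species barcode
    libraries with transition/transversion bias, planted diagnostic
    sites and optional planted non-monophyly, so every method can be
    validated against a known answer key.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
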