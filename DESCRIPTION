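Package: megakey
Title: Table-Based Descriptions and Multi-Access Identification for Megaselia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A streamlined, table-based description system for the enormous
    fly genus Megaselia (Diptera: Phoridae). Provides the canonical
    29-character morphological schema with coded character states and the
    measurement/classification rules behind them; parsers, validators and
    writers for single-taxon description documents in TSV and JSON dialects;
    a coded species-by-character matrix with keyword search over remarks; a
    tolerance-aware multi-access identification engine with an entropy-based
    best-next-character suggester; and a generator of synthetic species
    descriptions for testing identification workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
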