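Package: dichokey
Title: Single-Access Identification Keys: Encoding, Traversal, Inversion and Congruence
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An engine for single-access (dichotomous) identification keys:
    encode a key as a character ontology plus a couplet table, validate its
    tree structure, execute it against partial observations, and invert it
    into a taxon-by-character constraint matrix.  On top of the matrix the
    package offers polyclave (multi-access) identification with error
    tolerance and information-gain character selection, and a congruence
    analysis comparing key branches with reference clades and geographic
    regions.  Ships a complete transcription of a 71-couplet anatomical key
    to the palm genus Syagrus (leaflet margin anatomy) as a packaged fixture,
    together with reference clade and region tables, plus a seeded generator
    of random dichotomous keys with known ground truth for property-based
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools
Suggests: testthat (>= 3.0.0), ape, jsonlite, optparse, withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
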