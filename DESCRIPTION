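Package: synthenum
Title: Reaction-Based Combinatorial Library Enumeration and Diversity Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Toolkit for building virtual make-on-demand chemical libraries from
    SMARTS-encoded reaction definitions. Parses and validates reaction files
    (synthon inclusion/exclusion patterns, symmetric-reagent detectors, mapped
    reaction transforms), filters building-block catalogs by functional-group
    compatibility, purchasability tier and size, combinatorially enumerates
    products with provenance and purchasability coding, computes druglikeness
    descriptors (Lipinski/Veber gate, QED, Fsp3) and structural-alert flags
    (PAINS, Brenk-style, NIH-style), and runs diversity analytics: Bemis-Murcko
    scaffold census and overlap, principal-moments-of-inertia shape triangles,
    and InChIKey-partitioned identity search. Chemistry primitives (SMILES,
    SMARTS, InChIKey, 3D building) are provided by Open Babel, linked through
    Rcpp; the mapped-reaction transform engine is implemented in the package.
    Ships six built-in reaction definitions and a deterministic synthetic
    building-block generator for testing at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
SystemRequirements: Open Babel 3 (headers and shared library)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
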