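Package: rxnspace
Title: Exhaustive Enumeration of Amine-Acid Reaction Space via Bond-Order Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for exploring the reaction space between an amine and a
    carboxylic acid by exhaustive, valence-constrained enumeration of bond-order
    matrices over a fixed heavy-atom set. Molecular systems are encoded as
    symmetric integer adjacency matrices; reactions are encoded as signed
    transformation matrices (product minus starting material) and scored by bond
    edit distance. The package enumerates every octet-compliant, charge-free
    product of the eight-atom amine-acid system, deduplicates products under
    atom degeneracy, filters them by ring count and edit distance, computes
    physicochemical descriptors and principal-moment-of-inertia shape
    coordinates, applies the transformation library to substituted drug-like
    substrates for late-stage diversification, and searches enumerated products
    as substructures of compound libraries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    ChemmineR,
    ChemmineOB,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
SystemRequirements: OpenBabel (the obabel executable must be on the PATH)
Config/testthat/edition: 3
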