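Package: ppicomplex
Title: Template-Based Assembly of Multi-Subunit Protein Complex Models
    from Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts and builds structural models of multi-subunit protein
    complexes (supramolecules) by combining a library of experimentally
    determined binary complex structures with a protein-protein interaction
    network.  Binary templates whose chains are homologous to an interacting
    protein pair ("structure elements") are assembled into larger models by
    iterative superposition of shared subunits, with a TM-score/identity
    acceptance gate, steric clash rejection and alternative-interface
    bookkeeping.  Includes buried-surface-area interface detection and
    typing (experimentally determined, model-predicted, model-suggested;
    direct/indirect), a CAPRI-style virtual blind test, extrapolation of
    models to homologous subunit combinations, and mapping of amino-acid
    variants onto molecular environments with enrichment statistics.  A
    deterministic synthetic-fixture generator produces toy crystal
    structures, sequences, interaction tables and variants with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
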