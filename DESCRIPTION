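Package: relmat
Title: Relation Matrices and Structural Pattern Matching for RNA
    Secondary Structures with Pseudoknots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Represents RNA secondary structures and RNA-RNA interactions
    with arbitrary pseudoknots as arc diagrams, enumerates their loops, and
    classifies every loop pair as concatenated, nested, or crossing.  Each
    structure (or its core and shadow abstractions, obtained by collapsing
    helix stacks, dropping unpaired residues, and keeping only crossing
    arcs) maps to a strict upper-triangular relation matrix; a structural
    pattern is located by finding its matrix as a diagonal submatrix over
    windows of consecutive loops.  Includes Bpseq input/output with strict
    validation, strand-break annotation for interaction structures, seeded
    generators of random valid diagrams, a matrix-to-diagram realizer, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
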