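# relmat

Relation matrices and structural pattern matching for RNA secondary
structures — including arbitrary pseudoknots and RNA–RNA interactions.

## The problem

Functional RNA families conserve their secondary structure far better than
their sequence, so locating a known *structural* motif inside a larger
structure is a recurring task in structural bioinformatics.  Most exact
methods (tree matching, affix trees/arrays) require pseudoknot-free
structures; general arc-preserving subsequence search with pseudoknots is
NP-hard.  `relmat` implements a polynomial-time middle road: describe a
structure not by its arcs but by the *pairwise relations of its loops*,
and search for patterns in that description.

An RNA secondary structure is an **arc diagram**: residues 1..ℓ on a
backbone line, one arc (i, j) per base pair.  Each arc determines a
**loop**; loops are numbered L₁..L_N by ascending closing position.  For
two loops L_s = (i_s, j_s), L_t = (i_t, j_t) with j_s < j_t exactly one
relation holds:

| relation        | symbol | order condition           |
|-----------------|--------|---------------------------|
| concatenation   | ⊙ (`o`) | i_s < j_s < i_t < j_t    |
| nesting         | ⋒ (`n`) | i_t < i_s < j_s < j_t    |
| crossing        | ⨉ (`x`) | i_s < i_t < j_s < j_t    |

The strict upper triangle a_st (s < t) of the N×N **relation matrix**
encodes the whole loop topology; crossings are simply entries `x`, so
pseudoknots need no special treatment.  A pattern of M loops occurs in a
target of N loops wherever the pattern's matrix appears as a *diagonal
submatrix* over a window of M consecutive loop indices — a restricted
arc-preserving-subsequence semantics that respects the 5′→3′ folding
process (an arc closing inside the window is always retained; where it
opened is unconstrained).

Two coarser views of a structure are supported everywhere:

* **core** — delete unpaired residues, collapse each helix stack to one
  arc, renumber (keeps branching + pseudoknot topology, drops lengths);
* **shadow** — keep only arcs that cross at least one other arc, then
  collapse and renumber (the pseudoknot skeleton; empty iff the structure
  is pseudoknot-free).

RNA–RNA interactions are handled as one concatenated diagram plus a
strand-break position; every loop is classed `INTRA1`, `INTRA2`, or
`INTER`, and the relation matrix can be block-permuted to separate
intra-molecular from interaction relations.

## Worked example

```r
library(relmat)

# a 28-residue pseudoknotted structure bundled with the package
d <- parse_bpseq(relmat_example("pk28.bpseq"))
d
#> arc diagram: 28 vertices, 8 arcs
#>  arcs: (1,7) (2,6) (8,11) (12,24) (13,23) (14,17) (18,27) (19,22)

shadow_of(d)
#> arc diagram (abstraction): 4 vertices, 2 arcs
#>  arcs: (1,3) (2,4)          # the minimal crossing: one pseudoknot

core_of(d)
#> arc diagram (abstraction): 12 vertices, 6 arcs
#>  arcs: (1,2) (3,4) (5,11) (6,7) (8,12) (9,10)

# a six-loop structure and a three-loop pattern, as relation matrices
target  <- deserialize_matrix(relmat_example("sixloop_structure.tsv"))
pattern <- deserialize_matrix(relmat_example("threeloop_pattern.tsv"))
match_pattern(target, pattern)
#> 2 occurrence(s) of a 3-loop pattern in a 6-loop target
#>   1 2 3
#>   4 5 6
```

The two windows mean the pattern (L₁ crosses L₂ and L₃, L₂ nested in L₃)
occurs twice: once as target loops {1,2,3} and once as {4,5,6}.

The same works end-to-end from diagrams, at any abstraction level, and
with interaction annotation:

```r
duplex <- parse_bpseq(relmat_example("duplex19.bpseq"))   # strand break at 9
res <- match_structures(duplex, duplex, strand_break = 9)
res$classes[[1]]
#> [1] "INTRA1" "INTRA1" "INTER" "INTER" "INTRA2" "INTRA2" "INTRA2"
```

A command line mirrors the R surface (`exec/relmat` after installation):

```sh
relmat matrix pk28.bpseq --level shadow     # -> N 2 / 1 2 x
relmat match --target structure.bpseq --pattern pattern.tsv
relmat generate --length 30 --arcs 6 --crossing-bias 0.5 --seed 11
```

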