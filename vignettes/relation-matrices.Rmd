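---
title: "Loop relation matrices and structural matching in pseudoknotted RNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Loop relation matrices and structural matching in pseudoknotted RNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relmat)
```

## The model

A secondary structure over residues 1..ℓ is an arc diagram D = (ω, B):
the backbone is the ordered vertex set, ω the residue string, and B a set
of arcs (i, j), i < j, one per base pair.  Because a residue forms at
most one hydrogen bond, arc endpoints are pairwise distinct (vertex
degree ≤ 1 above the backbone), and because contiguous residues cannot
pair, j > i + 1 for real structures.  Each arc determines a loop; loops
are enumerated L₁..L_N by strictly ascending closing position, which is
well defined since closing positions are unique.

For two loops with j_s < j_t exactly one of three order relations holds —
concatenation (i_s < j_s < i_t < j_t), nesting (i_t < i_s < j_s < j_t),
or crossing (i_s < i_t < j_s < j_t).  This trichotomy is a counting
argument: of the orderings of the four distinct endpoints compatible with
i_s < j_s, i_t < j_t, and j_s < j_t, precisely these three remain.  The
strict upper triangle of the N×N matrix over {⊙, ⋒, ⨉} (serialized
`o`/`n`/`x`) therefore determines the loop topology uniquely, and a
structure is pseudoknotted iff the matrix contains a crossing entry.

```{r}
d <- parse_bpseq(relmat_example("duplex19.bpseq"))
build_relation_matrix(enumerate_loops(d))
```

## Matching semantics

A pattern with M loops occurs in a target with N loops at start s iff the
target entries over the window s..s+M−1 equal the pattern's matrix cell
for cell.  Windows of *consecutive* close-ordered loops implement a
restricted arc-preserving-subsequence search: every arc that closes
inside the window is part of the candidate substructure, while arcs are
free to open before it.  The asymmetry mirrors folding — a residue pairs
with one synthesized earlier — and it is what keeps the search polynomial
(O(N·M²) cell comparisons; the general arc-preserving subsequence
problem with pseudoknots is NP-hard).  Non-contiguous loop subsets are
deliberately out of scope.

`match_pattern()` scans windows column-major with a first-row fast filter
and early exit.  `brute_force_match()` implements the identical contract
with no optimizations — every window submatrix materialized and compared
in full.  Keeping two independent code paths lets the test suite assert
their equivalence on thousands of random instances, which is the
package's main guard against matcher regressions.  A scaling check counts
cell comparisons (not wall-clock time) over growing targets and asserts
at-most-quadratic growth.

## Abstractions

The core deletes unpaired residues, collapses each helix stack to a
single arc, and renumbers the surviving endpoints to 1..2K.  The shadow
first keeps only arcs that cross at least one other arc — crossing is
decided on the original coordinates — and then collapses and renumbers
likewise.  Stacks are maximal chains of immediately-nested arcs
(i₂ = i₁ + 1, j₂ = j₁ − 1 on the coordinates being collapsed).

One ordering choice here was genuinely open: whether parallelism is
evaluated on the original coordinates or after unpaired-vertex deletion.
We collapse **after deletion**.  The alternative is not idempotent: for
arcs {(1,12), (2,11), (3,8), (4,7)} the two original-coordinate stacks
collapse to representatives that become immediately nested once the
residues between them vanish, so a second application would merge them.
Deleting first and collapsing on the compacted coordinates provably
reaches a fixed point in one pass (any two representatives that ended up
adjacent-parallel would have belonged to one chain already), and the two
orders agree on every worked example we ship.  Both `core_of()` and
`shadow_of()` are therefore idempotent, which the randomized suite
asserts.

Two further conventions: the stack representative is the outermost arc —
provably irrelevant after renumbering, also property-tested — and
abstraction outputs carry an empty residue string and may contain
contiguous arcs such as (1,2), which real Bpseq input may not
(`arc_diagram(allow_contiguous = TRUE)` marks that distinction).

## RNA–RNA interactions

A duplex is one concatenated diagram plus a strand break n₁ (molecule 1
occupies 1..n₁).  A loop is `INTER` iff it opens at or before the break
and closes after it; otherwise `INTRA1`/`INTRA2` by side.
`permute_rri_matrix()` reorders rows and columns into the blocks INTRA1,
INTER, INTRA2, stable within blocks.  The block order is our convention,
chosen for reproducibility; relation entries travel with their loop pair,
so the permutation changes layout, never content.  When matching at core
or shadow level with a strand break, each abstract loop inherits the
class of its stack-representative arc in original coordinates.

## Synthetic data

`generate_diagram()` places K arcs one at a time on a length-L backbone.
With probability `crossing_bias` a new arc is forced to cross a random
existing arc; otherwise it is placed so that it crosses nothing, which
makes `crossing_bias = 0` a constructive guarantee of pseudoknot-freeness
rather than a statistical tendency.  All draws happen inside a
saved-and-restored RNG scope keyed by the config seed, so generation is
reproducible and never perturbs the caller's random stream.  Defaults in
the test suite span lengths 10–40 with roughly a third of residues
paired and biases 0–1, which covers nested, mixed, and densely crossing
regimes.  The generator emulates *valid* diagrams, not thermodynamics:
no stacking energies, no minimum hairpin sizes beyond the non-contiguity
rule, uniform residues.  Passing property tests on these inputs
demonstrates combinatorial correctness of the formalism, not biological
realism of any particular structure.

Near-saturated pseudoknot-free configurations (2K = L) are genuinely
infeasible — a non-crossing perfect matching forces an innermost adjacent
pair — and the generator reports them as such rather than silently
relaxing a constraint.

`realize_matrix()` inverts `build_relation_matrix()` where possible.  It
searches endpoint *orderings*: closes are append-only (loop order is
close order), and the relation of a new loop to each earlier one depends
only on where its open falls relative to that loop's endpoints, so each
earlier loop narrows the open's feasible insertion slots to an interval.
Backtracking over the remaining slots is exhaustive, so inconsistent
matrices (e.g. L₁ ⊙ L₂, L₂ ⊙ L₃, L₁ ⋒ L₃) fail with an explicit
infeasibility error.  Final coordinates are the smallest integers
consistent with the ordering, with one unpaired gap inside each innermost
arc to keep pairs non-contiguous.

## Numerical and degenerate-input choices

* Bpseq validation is strict and each failure mode has its own condition
  class; residues outside A/C/G/U (IUPAC codes, N placeholders) warn but
  parse.  Blank and `#` lines are skipped; anything else malformed is
  fatal.
* Loop enumeration ties cannot occur (closing positions are unique), so
  no tie-break rule is needed.
* An empty pattern is a usage error everywhere, as is a pattern whose
  shadow is empty when matching at shadow level; an empty *target* simply
  yields zero occurrences.
* Matrix equality is exact symbol equality on the strict upper triangle;
  there is no wildcard symbol and no similarity score — matching is
  exact by design.
* The bundled nine-loop example ships with placeholder N residues because
  only its arc set is specified; its printed six-arc core counterpart in
  the source material contains a vertex shared by two arcs, which is
  impossible under degree ≤ 1 — the package derives {(1,2), (3,4),
  (5,11), (6,7), (8,12), (9,10)} and a dedicated test documents the
  single-arc difference.

## Problem sizes in the test suite

The randomized suites use 1,000 matcher-vs-oracle instances (targets up
to 40 loops, patterns up to 8), 10,000 loop-pair trichotomy draws, 1,000
Bpseq round trips, and 100–160 realization round trips with up to 8
arcs; the full suite runs in well under a minute.  These sizes were
chosen to exercise every code path and boundary (window width 1, pattern
equal to target, saturated crossings) while remaining comfortable for
routine development runs.

## Limitations

* Matching is exact and structure-only; sequence-constrained and
  approximate matching are out of scope.
* Occurrences are windows of consecutive loops; motifs scattered across
  non-consecutive loops are not found (by design, see above).
* Dot-bracket and CT input are not parsed; Bpseq (or a serialized
  matrix) is the interchange format.
* Pairing chemistry (Watson–Crick/wobble legality) is not checked; the
  formalism is purely combinatorial.
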