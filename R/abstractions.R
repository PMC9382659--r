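# Core and shadow abstractions.  Operation order follows the definitions:
# first delete vertices (unpaired ones, and for the shadow the endpoints
# of non-crossing arcs — crossing is decided on the ORIGINAL coordinates),
# then collapse parallel stacks on the post-deletion coordinates, then
# renumber.  Collapsing after deletion is what makes both abstractions
# idempotent: stacks that only become parallel once the residues between
# them vanish are merged, and a second application finds nothing to do.

arcs_of <- function(x) {
  if (is_arc_diagram(x)) x$arcs else as_arc_matrix(x)
}

# delete unpaired vertices, collapse stacks on the compacted coordinates,
# renumber; returns the abstraction plus, for each of its arcs, the stack
# representative in original coordinates (row-aligned, sorted by open)
collapse_deleted <- function(arcs) {
  arcs <- as_arc_matrix(arcs)
  if (nrow(arcs) == 0) {
    return(list(diagram = arc_diagram(0), sources = arcs))
  }
  compact <- renumber_arcs(arcs)$arcs  # row-aligned with arcs (open order)
  reps <- collapse_stacks(compact)$representatives
  rows <- match(paste(reps[, 1], reps[, 2]),
                paste(compact[, 1], compact[, 2]))
  list(diagram = renumber_arcs(reps),
       sources = arcs[rows, , drop = FALSE])
}

# TRUE at [s, t] iff arc s opens before arc t and they interleave:
# open_s < open_t < close_s < close_t.
crossing_matrix <- function(arcs) {
  n <- nrow(arcs)
  if (n < 2) return(matrix(FALSE, n, n))
  o <- arcs[, 1]; cl <- arcs[, 2]
  outer(o, o, "<") & outer(cl, o, ">") & outer(cl, cl, "<")
}

#' Partition arcs into helix stacks
#'
#' Two arcs (i1, j1), (i2, j2) are parallel iff the second sits
#' immediately inside the first: i2 = i1 + 1 and j2 = j1 - 1 (or vice
#' versa).  Maximal chains of parallel arcs are the helix stacks; each
#' collapses to a single representative arc.
#'
#' @param arcs An arc set (two-column matrix, list of pairs, or an
#'   [arc_diagram()]).
#' @param representative Which member stands for the stack: the
#'   `"outermost"` (minimal open, maximal close; the default) or the
#'   `"innermost"`.  After renumbering the choice is provably irrelevant.
#' @return An object of class `stack_partition`: a list with `stacks` (a
#'   list of two-column matrices, members ordered outermost to innermost)
#'   and `representatives` (one arc per stack, as a two-column matrix
#'   sorted by open position).
#' @examples
#' collapse_stacks(list(c(1, 8), c(2, 7), c(3, 6)))
#' @export
collapse_stacks <- function(arcs, representative = c("outermost", "innermost")) {
  representative <- match.arg(representative)
  arcs <- arcs_of(arcs)
  n <- nrow(arcs)
  if (n == 0) {
    return(structure(list(stacks = list(), representatives = arcs),
                     class = "stack_partition"))
  }
  key <- paste(arcs[, 1], arcs[, 2])
  row_of <- stats::setNames(seq_len(n), key)
  has <- function(i, j) !is.na(row_of[paste(i, j)])
  roots <- which(!mapply(function(i, j) has(i - 1L, j + 1L),
                         arcs[, 1], arcs[, 2]))
  stacks <- lapply(roots, function(r) {
    members <- r
    i <- arcs[r, 1]; j <- arcs[r, 2]
    while (has(i + 1L, j - 1L)) {
      i <- i + 1L; j <- j - 1L
      members <- c(members, row_of[[paste(i, j)]])
    }
    arcs[members, , drop = FALSE]
  })
  reps <- do.call(rbind, lapply(stacks, function(s) {
    if (representative == "outermost") s[1, , drop = FALSE]
    else s[nrow(s), , drop = FALSE]
  }))
  reps <- reps[order(reps[, 1]), , drop = FALSE]
  structure(list(stacks = stacks, representatives = reps),
            class = "stack_partition")
}

#' @export
print.stack_partition <- function(x, ...) {
  cat(sprintf("%d stack(s)\n", length(x$stacks)))
  for (k in seq_along(x$stacks)) {
    s <- x$stacks[[k]]
    cat(sprintf("  [%d] %s\n", k,
                paste0("(", s[, 1], ",", s[, 2], ")", collapse = " ")))
  }
  invisible(x)
}

#' Renumber an arc set onto its surviving endpoints
#'
#' Replaces every endpoint by its 1-based rank among all surviving
#' endpoints sorted ascending.  The result is an abstraction: an arc
#' diagram with an empty sequence and length 2 * (number of arcs), with no
#' unpaired vertices.
#'
#' @param arcs An arc set (matrix, list of pairs, or [arc_diagram()]).
#' @return An [arc_diagram()] (possibly containing contiguous arcs).
#' @examples
#' renumber_arcs(list(c(12, 24), c(18, 27)))  # -> (1,3), (2,4)
#' @export
renumber_arcs <- function(arcs) {
  arcs <- arcs_of(arcs)
  if (nrow(arcs) == 0) return(arc_diagram(0))
  rank <- match(arcs, sort(c(arcs)))
  dim(rank) <- dim(arcs)
  arc_diagram(2L * nrow(arcs), rank, allow_contiguous = TRUE)
}

#' Core of an arc diagram
#'
#' The core deletes every unpaired residue, then collapses each helix
#' stack (maximal parallel chain on the post-deletion coordinates) to a
#' single arc and renumbers.  It preserves the branching and pseudoknot
#' topology of the structure while discarding helix lengths and loop
#' sizes, and is idempotent: the core of a core is itself.
#'
#' @param diagram An [arc_diagram()].
#' @return An [arc_diagram()] abstraction with no unpaired vertices and no
#'   parallel arcs.
#' @export
core_of <- function(diagram) {
  stopifnot(is_arc_diagram(diagram))
  collapse_deleted(diagram$arcs)$diagram
}

#' Shadow of an arc diagram
#'
#' The shadow keeps exactly the arcs that cross at least one other arc of
#' the diagram (tested on original coordinates), deletes all other
#' vertices, collapses stacks among the kept arcs on the post-deletion
#' coordinates, and renumbers.  It isolates the pseudoknot skeleton: the
#' shadow is empty iff the structure is pseudoknot-free, and the shadow of
#' a shadow is itself.
#'
#' @param diagram An [arc_diagram()].
#' @return An [arc_diagram()] abstraction.
#' @export
shadow_of <- function(diagram) {
  stopifnot(is_arc_diagram(diagram))
  cm <- crossing_matrix(diagram$arcs)
  keep <- rowSums(cm) + colSums(cm) > 0
  collapse_deleted(diagram$arcs[keep, , drop = FALSE])$diagram
}

#' Is a structure pseudoknotted?
#'
#' TRUE iff some pair of arcs crosses (open_s < open_t < close_s <
#' close_t); equivalently, iff the shadow is non-empty.
#'
#' @param diagram An [arc_diagram()].
#' @return A logical scalar.
#' @export
is_pseudoknotted <- function(diagram) {
  stopifnot(is_arc_diagram(diagram))
  any(crossing_matrix(diagram$arcs))
}

# Abstraction plus the representative arcs in ORIGINAL coordinates, row-
# aligned with the abstraction's arcs (both sorted by open position; rank
# renumbering preserves that order).  Used to carry strand-break classes
# through core/shadow matching.
abstract_with_sources <- function(diagram, level) {
  switch(level,
    structure = list(diagram = diagram, sources = diagram$arcs),
    core = collapse_deleted(diagram$arcs),
    shadow = {
      cm <- crossing_matrix(diagram$arcs)
      keep <- rowSums(cm) + colSums(cm) > 0
      collapse_deleted(diagram$arcs[keep, , drop = FALSE])
    },
    stop_relmat(sprintf("unknown abstraction level '%s'", level),
                "relmat_usage_error")
  )
}
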