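# Structural relation matching: a pattern of M loops occurs in a target of
# N loops at start s iff the target's entries over the window of M
# consecutive loop indices s..s+M-1 equal the pattern's matrix cell for
# cell.  Windows of consecutive close-ordered loops realize a restricted
# arc-preserving-subsequence search: every arc closing inside the window
# is retained (its close position ranks it into the window), while arcs
# opening earlier are unconstrained — mirroring the 5'->3' folding process
# in which a residue pairs only with one already synthesized.

new_match_result <- function(starts, pattern_size, target_size,
                             classes = NULL) {
  structure(list(starts = as.integer(starts),
                 pattern_size = as.integer(pattern_size),
                 target_size = as.integer(target_size),
                 classes = classes),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("%d occurrence(s) of a %d-loop pattern in a %d-loop target\n",
              length(x$starts), x$pattern_size, x$target_size))
  for (k in seq_along(x$starts)) {
    w <- x$starts[k] + seq_len(x$pattern_size) - 1L
    line <- paste(w, collapse = " ")
    if (!is.null(x$classes)) {
      line <- paste0(line, "  [", paste(x$classes[[k]], collapse = ","), "]")
    }
    cat(" ", line, "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.match_result <- function(x, ...) {
  data.frame(start = x$starts,
             loops = vapply(x$starts, function(s) {
               paste(s + seq_len(x$pattern_size) - 1L, collapse = ",")
             }, character(1)))
}

check_match_args <- function(target, pattern) {
  stopifnot(inherits(target, "relation_matrix"),
            inherits(pattern, "relation_matrix"))
  if (pattern$n < 1) {
    stop_relmat("empty pattern: the pattern must contain at least one loop",
                "relmat_usage_error")
  }
}

#' Locate a pattern matrix inside a target relation matrix
#'
#' Reports every start index s (1 <= s <= N - M + 1) whose window of M
#' consecutive target loops induces a submatrix identical to the pattern's
#' matrix.  Comparison is column-major with a first-row fast filter and
#' early exit on the first mismatching cell.  A 1-loop pattern matches
#' every loop; overlapping occurrences are all reported, ascending.
#'
#' @param target,pattern `relation_matrix` objects (M >= 1 pattern loops).
#' @param count_comparisons When TRUE the result carries an attribute
#'   `comparisons` with the number of cell comparisons performed (used to
#'   check the algorithm's scaling without relying on wall-clock times).
#' @return A `match_result` with fields `starts`, `pattern_size`,
#'   `target_size`.
#' @seealso [brute_force_match()] for the unoptimized reference search,
#'   [match_structures()] to match two arc diagrams directly.
#' @export
match_pattern <- function(target, pattern, count_comparisons = FALSE) {
  check_match_args(target, pattern)
  m <- pattern$n; n <- target$n
  tm <- target$mat; pm <- pattern$mat
  comparisons <- 0L
  starts <- integer(0)
  if (n >= m) {
    for (s in seq_len(n - m + 1L)) {
      ok <- TRUE
      if (m >= 2) {
        for (b in 2:m) {  # first-row fast filter
          comparisons <- comparisons + 1L
          if (tm[s, s + b - 1L] != pm[1L, b]) { ok <- FALSE; break }
        }
        if (ok && m >= 3) {
          for (b in 3:m) {
            for (a in 2:(b - 1L)) {
              comparisons <- comparisons + 1L
              if (tm[s + a - 1L, s + b - 1L] != pm[a, b]) { ok <- FALSE; break }
            }
            if (!ok) break
          }
        }
      }
      if (ok) starts <- c(starts, s)
    }
  }
  out <- new_match_result(starts, m, n)
  if (count_comparisons) attr(out, "comparisons") <- comparisons
  out
}

#' Brute-force reference matcher
#'
#' Same contract as [match_pattern()], implemented independently: every
#' window's full submatrix is materialized and compared cell by cell with
#' no early exit and no filtering.  Kept as the in-package oracle for
#' equivalence testing.
#'
#' @inheritParams match_pattern
#' @return A `match_result`.
#' @export
brute_force_match <- function(target, pattern) {
  check_match_args(target, pattern)
  m <- pattern$n; n <- target$n
  ut <- upper.tri(pattern$mat)
  pcells <- pattern$mat[ut]
  starts <- integer(0)
  if (n >= m) {
    for (s in seq_len(n - m + 1L)) {
      sub <- target$mat[s:(s + m - 1L), s:(s + m - 1L), drop = FALSE]
      if (all(sub[ut] == pcells)) starts <- c(starts, s)
    }
  }
  new_match_result(starts, m, n)
}

#' Match a structural pattern between two arc diagrams
#'
#' Applies the chosen abstraction (`structure`, `core`, or `shadow`) to
#' both target and pattern, enumerates loops, builds both relation
#' matrices, and runs [match_pattern()].  A pattern given directly as a
#' `relation_matrix` bypasses abstraction.  With `strand_break`, the
#' target is treated as an RNA-RNA interaction and each occurrence is
#' annotated with the classes (`INTRA1`/`INTER`/`INTRA2`) of its loops;
#' for core/shadow levels each abstract loop inherits the class of its
#' stack-representative arc in original coordinates.
#'
#' @param target An [arc_diagram()].
#' @param pattern An [arc_diagram()] or a `relation_matrix`.
#' @param level Abstraction applied to both sides: `"structure"` (default),
#'   `"core"`, or `"shadow"`.
#' @param strand_break Optional strand-break position of the target duplex.
#' @return A `match_result`; `classes` is a list (one character vector per
#'   occurrence) when `strand_break` is given.
#' @export
match_structures <- function(target, pattern,
                             level = c("structure", "core", "shadow"),
                             strand_break = NULL) {
  level <- match.arg(level)
  stopifnot(is_arc_diagram(target))
  at <- abstract_with_sources(target, level)
  tloops <- enumerate_loops(at$diagram)
  tmat <- build_relation_matrix(tloops)
  if (inherits(pattern, "relation_matrix")) {
    pmat <- pattern
  } else {
    stopifnot(is_arc_diagram(pattern))
    pd <- abstract_with_sources(pattern, level)$diagram
    if (nrow(pd$arcs) == 0) {
      stop_relmat(sprintf(
        "pattern is empty at level '%s' (e.g. the shadow of a pseudoknot-free structure); supply a pattern with at least one %s arc",
        level, level),
        "relmat_usage_error")
    }
    pmat <- build_relation_matrix(enumerate_loops(pd))
  }
  res <- match_pattern(tmat, pmat)
  if (!is.null(strand_break)) {
    # classes of the ABSTRACT loops, via their source arcs
    src <- at$sources
    sb <- as.integer(strand_break)
    if (is.na(sb) || sb < 1L || sb >= target$length) {
      stop_relmat("strand_break must satisfy 1 <= strand_break < length",
                  "relmat_strand_break")
    }
    # loops are close-ordered over renumbered coords; map each back to its
    # source row (arcs and sources are row-aligned, sorted by open)
    row_for <- match(tloops$open, at$diagram$arcs[, 1])
    cls <- ifelse(src[row_for, 2] <= sb, "INTRA1",
           ifelse(src[row_for, 1] > sb, "INTRA2", "INTER"))
    res$classes <- lapply(res$starts, function(s) {
      cls[s + seq_len(pmat$n) - 1L]
    })
    res$loop_classes <- cls
  }
  res
}
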