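`%||%` <- function(a, b) if (is.null(a)) b else a

stop_relmat <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "relmat_error", "error", "condition")))
}

warn_relmat <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "relmat_warning", "warning", "condition")))
}

as_arc_matrix <- function(arcs) {
  if (is.null(arcs) || (is.matrix(arcs) && nrow(arcs) == 0) ||
      (is.list(arcs) && length(arcs) == 0)) {
    return(matrix(integer(), 0, 2, dimnames = list(NULL, c("open", "close"))))
  }
  if (is.list(arcs) && !is.data.frame(arcs)) {
    arcs <- do.call(rbind, lapply(arcs, function(p) as.integer(p[1:2])))
  }
  if (is.data.frame(arcs)) arcs <- as.matrix(arcs[, 1:2])
  if (!is.matrix(arcs) || ncol(arcs) != 2) {
    stop_relmat("arcs must be pairs (i, j) given as a two-column matrix or list",
                "relmat_invalid_arc")
  }
  storage.mode(arcs) <- "integer"
  arcs <- arcs[order(arcs[, 1]), , drop = FALSE]
  dimnames(arcs) <- list(NULL, c("open", "close"))
  arcs
}

#' Arc diagram of an RNA secondary structure
#'
#' An arc diagram places the residues 1..length on a backbone line and draws
#' one arc (i, j), i < j, above it for each base pair.  It represents a
#' plain secondary structure, a concatenated RNA-RNA duplex, or an
#' abstraction (core or shadow) of either; abstractions carry an empty
#' sequence.
#'
#' @param length Number of backbone vertices (residues); may be 0 for the
#'   empty diagram.
#' @param arcs Base pairs as a two-column matrix (or list of pairs) of
#'   1-based positions, open < close.  Endpoints must be pairwise distinct:
#'   a residue pairs with at most one partner.
#' @param sequence Residue string (length must equal `length`), or `""` for
#'   abstractions where residues have been deleted.
#' @param allow_contiguous Permit arcs with close == open + 1.  Real base
#'   pairs between backbone-adjacent residues are impossible and rejected by
#'   default; the core/shadow abstractions legitimately contain such arcs
#'   after renumbering and set this flag.
#' @return An object of class `arc_diagram` with fields `length`,
#'   `sequence`, `arcs`.
#' @examples
#' arc_diagram(5, list(c(2, 5)), "GAUCU")
#' @export
arc_diagram <- function(length, arcs = NULL, sequence = "",
                        allow_contiguous = FALSE) {
  length <- as.integer(length)
  if (is.na(length) || length < 0) {
    stop_relmat("length must be a non-negative integer", "relmat_invalid_diagram")
  }
  arcs <- as_arc_matrix(arcs)
  sequence <- toupper(as.character(sequence %||% ""))
  if (nrow(arcs) > 0) {
    if (any(arcs[, 1] >= arcs[, 2])) {
      stop_relmat("every arc (i, j) must satisfy i < j", "relmat_invalid_arc")
    }
    if (any(arcs < 1L) || any(arcs > length)) {
      stop_relmat("arc endpoints must lie in 1..length", "relmat_invalid_arc")
    }
    if (!allow_contiguous && any(arcs[, 2] == arcs[, 1] + 1L)) {
      stop_relmat("contiguous residues cannot pair (close == open + 1)",
                  "relmat_contiguous_arc")
    }
    ends <- c(arcs)
    if (anyDuplicated(ends)) {
      stop_relmat("a residue occurs in more than one arc (degree > 1)",
                  "relmat_arc_degree")
    }
  }
  if (nzchar(sequence) && nchar(sequence) != length) {
    stop_relmat(sprintf("sequence has %d residues but length is %d",
                        nchar(sequence), length),
                "relmat_sequence_length")
  }
  structure(list(length = length, sequence = sequence, arcs = arcs),
            class = "arc_diagram")
}

#' @export
print.arc_diagram <- function(x, ...) {
  kind <- if (nzchar(x$sequence)) "arc diagram" else "arc diagram (abstraction)"
  cat(sprintf("%s: %d vertices, %d arcs\n", kind, x$length, nrow(x$arcs)))
  if (nrow(x$arcs) > 0) {
    pairs <- paste0("(", x$arcs[, 1], ",", x$arcs[, 2], ")")
    cat(" arcs:", paste(pairs, collapse = " "), "\n")
  }
  invisible(x)
}

is_arc_diagram <- function(x) inherits(x, "arc_diagram")

#' Enumerate the loops of an arc diagram
#'
#' Each arc (i, j) determines one loop.  Loops are indexed 1..N by strictly
#' ascending closing position j: the first loop is the one whose last paired
#' residue is leftmost along the backbone.  Closing positions are unique
#' (each residue pairs at most once), so the enumeration is deterministic.
#'
#' @param diagram An [arc_diagram()].
#' @return A data frame with columns `index`, `open`, `close`, one row per
#'   loop, ordered by `index`.
#' @examples
#' d <- arc_diagram(7, list(c(1, 5), c(2, 7)), allow_contiguous = TRUE)
#' enumerate_loops(d)
#' @export
enumerate_loops <- function(diagram) {
  stopifnot(is_arc_diagram(diagram))
  a <- diagram$arcs
  if (nrow(a) == 0) {
    return(data.frame(index = integer(), open = integer(), close = integer()))
  }
  ord <- order(a[, 2])
  data.frame(index = seq_len(nrow(a)),
             open = a[ord, 1],
             close = a[ord, 2])
}

#' Annotate an RNA-RNA interaction diagram with a strand break
#'
#' An interaction between two RNAs is encoded as a single diagram over the
#' concatenation of the two molecules; `strand_break` is the last position
#' of molecule 1.  Every loop is classified as `INTRA1` (entirely within
#' molecule 1: close <= break), `INTRA2` (entirely within molecule 2:
#' open > break), or `INTER` (an interaction pair spanning the break:
#' open <= break < close).
#'
#' @param diagram An [arc_diagram()] over the concatenated duplex.
#' @param strand_break 1-based position n1 with 1 <= n1 < length; molecule 1
#'   occupies 1..n1.
#' @return An object of class `rri_annotation`: a list with `strand_break`
#'   and `loops` (the loop table of [enumerate_loops()] plus a `class`
#'   column).
#' @export
annotate_rri <- function(diagram, strand_break) {
  stopifnot(is_arc_diagram(diagram))
  strand_break <- as.integer(strand_break)
  if (is.na(strand_break) || strand_break < 1L ||
      strand_break >= diagram$length) {
    stop_relmat("strand_break must satisfy 1 <= strand_break < length",
                "relmat_strand_break")
  }
  loops <- enumerate_loops(diagram)
  loops$class <- ifelse(loops$close <= strand_break, "INTRA1",
                 ifelse(loops$open > strand_break, "INTRA2", "INTER"))
  structure(list(strand_break = strand_break, loops = loops),
            class = "rri_annotation")
}

#' @export
print.rri_annotation <- function(x, ...) {
  cat(sprintf("RNA-RNA interaction annotation, strand break at %d\n",
              x$strand_break))
  print(x$loops)
  invisible(x)
}
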