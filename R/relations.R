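# Loop relations and the relation matrix.
#
# For loops L_s = (i_s, j_s), L_t = (i_t, j_t) with j_s < j_t, exactly one
# of three order relations holds:
#   concatenation (o):  i_s < j_s < i_t < j_t
#   nesting       (n):  i_t < i_s < j_s < j_t
#   crossing      (x):  i_s < i_t < j_s < j_t
# The strict upper triangle of the N x N matrix over these symbols
# determines the structure's loop topology uniquely.

#' Relation symbols
#'
#' The three possible relations between two loops, serialized as single
#' characters: `o` (concatenation), `n` (nesting), `x` (crossing).
#' @format A named character vector `c(CONCAT = "o", NEST = "n", CROSS = "x")`.
#' @export
relation_symbols <- c(CONCAT = "o", NEST = "n", CROSS = "x")

as_loop <- function(x, what) {
  if (is.data.frame(x)) x <- c(x$open[1], x$close[1])
  x <- as.integer(x[1:2])
  if (anyNA(x) || x[1] >= x[2]) {
    stop_relmat(sprintf("%s is not a valid loop (open < close required)", what),
                "relmat_relation_error")
  }
  x
}

#' Classify the relation between two loops
#'
#' `a` must close before `b` (a.close < b.close, the loop-enumeration
#' order) and the four endpoints must be distinct; exactly one of the
#' three relations then holds.
#'
#' @param a,b Loops, each as a `c(open, close)` pair or a one-row loop
#'   table row.
#' @return One of `"o"` (concatenation), `"n"` (nesting: `a` inside `b`),
#'   `"x"` (crossing).
#' @examples
#' classify_relation(c(2, 6), c(4, 11))   # "x"
#' classify_relation(c(22, 27), c(21, 28))  # "n"
#' @export
classify_relation <- function(a, b) {
  a <- as_loop(a, "a"); b <- as_loop(b, "b")
  if (a[2] >= b[2]) {
    stop_relmat("a must close before b (a.close < b.close)",
                "relmat_relation_error")
  }
  if (anyDuplicated(c(a, b))) {
    stop_relmat("loops must not share endpoints", "relmat_relation_error")
  }
  if (a[2] < b[1]) "o" else if (b[1] < a[1]) "n" else "x"
}

new_relation_matrix <- function(n, mat, labels = seq_len(n)) {
  structure(list(n = as.integer(n), mat = mat, labels = as.integer(labels)),
            class = "relation_matrix")
}

#' Build the relation matrix of a loop set
#'
#' Fills the strict upper triangle: entry (s, t), s < t, is the relation
#' symbol between loops L_s and L_t of the close-ordered enumeration.
#' Runs in O(N^2) via vectorized endpoint comparisons.
#'
#' @param loops Loop table from [enumerate_loops()] (columns `open`,
#'   `close`, ordered by ascending close).
#' @return An object of class `relation_matrix`: a list with `n`, `mat`
#'   (N x N character matrix, `NA` on and below the diagonal), and
#'   `labels` (loop indices the rows refer to; 1..N until permuted).
#' @export
build_relation_matrix <- function(loops) {
  if (is_arc_diagram(loops)) loops <- enumerate_loops(loops)
  n <- nrow(loops)
  mat <- matrix(NA_character_, n, n)
  if (n >= 2) {
    if (is.unsorted(loops$close, strictly = TRUE)) {
      stop_relmat("loops must be ordered by strictly ascending close position",
                  "relmat_relation_error")
    }
    idx <- which(upper.tri(mat), arr.ind = TRUE)
    s <- idx[, 1]; t <- idx[, 2]
    os <- loops$open[s]; cs <- loops$close[s]; ot <- loops$open[t]
    mat[idx] <- ifelse(cs < ot, "o", ifelse(ot < os, "n", "x"))
  }
  new_relation_matrix(n, mat)
}

#' @export
print.relation_matrix <- function(x, ...) {
  cat(sprintf("relation matrix: %d loop(s), %d entries\n",
              x$n, x$n * (x$n - 1) / 2))
  if (x$n > 1) {
    shown <- x$mat
    shown[is.na(shown)] <- "."
    dimnames(shown) <- list(paste0("L", x$labels), paste0("L", x$labels))
    print(shown, quote = FALSE)
  }
  invisible(x)
}

relation_entries <- function(m) {
  if (m$n < 2) {
    return(data.frame(s = integer(), t = integer(), sym = character()))
  }
  idx <- which(upper.tri(m$mat), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(s = idx[, 1], t = idx[, 2], sym = m$mat[idx])
}

#' Reorder an interaction relation matrix into molecular blocks
#'
#' For an RNA-RNA interaction, rows and columns are permuted into three
#' blocks — loops internal to molecule 1 (`INTRA1`), interaction loops
#' spanning the strand break (`INTER`), then loops internal to molecule 2
#' (`INTRA2`) — preserving the original relative order within each block.
#' Entries travel with their loop pair: the relation between two loops is
#' unchanged, only its matrix position moves.  `labels` records the
#' original loop index of each row.
#'
#' @param matrix A `relation_matrix` over loops 1..N.
#' @param annotation An `rri_annotation` from [annotate_rri()] covering the
#'   same N loops, or a character vector of classes (one per loop index).
#' @return A `relation_matrix` with permuted `labels` and an attribute
#'   `blocks` giving the three block sizes.
#' @export
permute_rri_matrix <- function(matrix, annotation) {
  stopifnot(inherits(matrix, "relation_matrix"))
  classes <- if (inherits(annotation, "rri_annotation")) {
    annotation$loops$class[order(annotation$loops$index)]
  } else {
    as.character(annotation)
  }
  if (length(classes) != matrix$n ||
      !all(classes %in% c("INTRA1", "INTRA2", "INTER"))) {
    stop_relmat("annotation must give a class for each of the matrix's loops",
                "relmat_usage_error")
  }
  ord <- c(which(classes == "INTRA1"), which(classes == "INTER"),
           which(classes == "INTRA2"))
  n <- matrix$n
  mat <- base::matrix(NA_character_, n, n)
  if (n >= 2) {
    idx <- which(upper.tri(mat), arr.ind = TRUE)
    a <- ord[idx[, 1]]; b <- ord[idx[, 2]]
    mat[idx] <- matrix$mat[cbind(pmin(a, b), pmax(a, b))]
  }
  out <- new_relation_matrix(n, mat, labels = matrix$labels[ord])
  attr(out, "blocks") <- c(INTRA1 = sum(classes == "INTRA1"),
                           INTER = sum(classes == "INTER"),
                           INTRA2 = sum(classes == "INTRA2"))
  out
}

#' Serialize a relation matrix as TSV text
#'
#' Canonical form: a header line `N <n>`, then one line `s TAB t TAB c` per
#' strict-upper-triangle entry, (s, t) ascending lexicographically, with
#' `c` in `o`/`n`/`x`.  [deserialize_matrix()] inverts it exactly.
#'
#' @param matrix A `relation_matrix`.
#' @param path Optional file path to also write the text to.
#' @return The serialized text as a single string.
#' @export
serialize_matrix <- function(matrix, path = NULL) {
  stopifnot(inherits(matrix, "relation_matrix"))
  e <- relation_entries(matrix)
  txt <- paste0(paste(c(sprintf("N %d", matrix$n),
                        sprintf("%d\t%d\t%s", e$s, e$t, e$sym)),
                      collapse = "\n"), "\n")
  if (!is.null(path)) {
    cat(txt, file = path)
    return(invisible(txt))
  }
  txt
}

#' Read a serialized relation matrix
#'
#' @param x Path to a file, or the serialized text itself.
#' @return A `relation_matrix`.
#' @export
deserialize_matrix <- function(x) {
  lines <- bpseq_lines(x)  # same comment/blank-line conventions
  if (length(lines) == 0) {
    stop_relmat("empty relation-matrix input", "relmat_matrix_format")
  }
  head_f <- strsplit(lines[1], "[ \t]+")[[1]]
  n <- suppressWarnings(as.integer(head_f[2]))
  if (length(head_f) != 2 || head_f[1] != "N" || is.na(n) || n < 0) {
    stop_relmat("relation-matrix input must start with a header 'N <count>'",
                "relmat_matrix_format")
  }
  body <- lines[-1]
  if (length(body) != n * (n - 1) / 2) {
    stop_relmat(sprintf("expected %d entries for N = %d, found %d",
                        n * (n - 1) / 2, n, length(body)),
                "relmat_matrix_format")
  }
  mat <- matrix(NA_character_, n, n)
  if (length(body) > 0) {
    f <- strsplit(body, "[ \t]+")
    if (any(vapply(f, length, 1L) != 3L)) {
      stop_relmat("each entry line must be 's t c'", "relmat_matrix_format")
    }
    fm <- do.call(rbind, f)
    s <- suppressWarnings(as.integer(fm[, 1]))
    t <- suppressWarnings(as.integer(fm[, 2]))
    sym <- fm[, 3]
    if (anyNA(s) || anyNA(t) || any(s < 1 | t > n | s >= t)) {
      stop_relmat("entry indices must satisfy 1 <= s < t <= N",
                  "relmat_matrix_format")
    }
    if (anyDuplicated(paste(s, t))) {
      stop_relmat("duplicate (s, t) entry", "relmat_matrix_format")
    }
    if (!all(sym %in% relation_symbols)) {
      stop_relmat("relation symbols must be one of o, n, x",
                  "relmat_matrix_format")
    }
    mat[cbind(s, t)] <- sym
  }
  new_relation_matrix(n, mat)
}
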