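# Bpseq: three whitespace-separated columns per residue —
# position (1..l, ascending), base letter, partner position (0 = unpaired).
# Comment lines start with '#'; blank lines are skipped; anything else
# malformed is fatal.

bpseq_lines <- function(x) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    x <- readLines(x, warn = FALSE)
  } else if (length(x) == 1) {
    x <- strsplit(x, "\n", fixed = TRUE)[[1]]
  }
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read a Bpseq secondary structure
#'
#' Parses Bpseq text into a validated [arc_diagram()].  Validation is
#' strict: positions must be exactly 1..l in ascending order, pairing must
#' be reciprocal and non-self, and backbone-adjacent residues may not pair.
#' Each failure raises a distinct condition class
#' (`relmat_bpseq_malformed`, `relmat_bpseq_duplicate_position`,
#' `relmat_bpseq_missing_position`, `relmat_bpseq_self_pairing`,
#' `relmat_bpseq_contiguous_pairing`, `relmat_bpseq_partner_range`,
#' `relmat_bpseq_nonreciprocal`), all inheriting from `relmat_error`.
#'
#' Residue letters outside A, C, G, U (IUPAC ambiguity codes, N
#' placeholders) are tolerated with a warning of class
#' `relmat_base_warning`.
#'
#' @param x Path to a Bpseq file, or the Bpseq text itself (a single string
#'   with newlines, or a character vector of lines).
#' @return An [arc_diagram()].
#' @examples
#' parse_bpseq("1 G 0\n2 A 5\n3 U 0\n4 C 0\n5 U 2")
#' @export
parse_bpseq <- function(x) {
  lines <- bpseq_lines(x)
  if (length(lines) == 0) return(arc_diagram(0))
  fields <- strsplit(lines, "[ \t]+")
  bad <- vapply(fields, length, 1L) != 3L
  if (any(bad)) {
    stop_relmat(sprintf("malformed Bpseq line (expected 3 fields): '%s'",
                        lines[which(bad)[1]]),
                "relmat_bpseq_malformed")
  }
  m <- do.call(rbind, fields)
  pos <- suppressWarnings(as.integer(m[, 1]))
  partner <- suppressWarnings(as.integer(m[, 3]))
  if (anyNA(pos) || anyNA(partner)) {
    i <- which(is.na(pos) | is.na(partner))[1]
    stop_relmat(sprintf("non-integer position or partner field: '%s'", lines[i]),
                "relmat_bpseq_malformed")
  }
  base <- m[, 2]
  if (any(nchar(base) != 1L)) {
    stop_relmat("base field must be a single letter", "relmat_bpseq_malformed")
  }
  n <- length(pos)
  if (anyDuplicated(pos)) {
    stop_relmat(sprintf("duplicate position %d", pos[anyDuplicated(pos)]),
                "relmat_bpseq_duplicate_position")
  }
  if (!identical(pos, seq_len(n))) {
    stop_relmat("positions must be exactly 1..l in ascending order",
                "relmat_bpseq_missing_position")
  }
  if (any(partner < 0L | partner > n)) {
    stop_relmat("partner position outside 1..l",
                "relmat_bpseq_partner_range")
  }
  if (any(partner == pos)) {
    stop_relmat(sprintf("residue %d pairs with itself",
                        pos[which(partner == pos)[1]]),
                "relmat_bpseq_self_pairing")
  }
  paired <- partner > 0L
  if (any(paired & abs(partner - pos) == 1L)) {
    stop_relmat("contiguous residues cannot pair (|partner - position| == 1)",
                "relmat_bpseq_contiguous_pairing")
  }
  recip <- partner[paired]
  if (any(partner[recip] != pos[paired])) {
    i <- pos[paired][which(partner[recip] != pos[paired])[1]]
    stop_relmat(sprintf(
      "non-reciprocal pairing: position %d says %d but %d does not point back",
      i, partner[i], partner[i]),
      "relmat_bpseq_nonreciprocal")
  }
  odd <- setdiff(unique(toupper(base)), c("A", "C", "G", "U"))
  if (length(odd) > 0) {
    warn_relmat(sprintf("tolerated non-AUGC base letters: %s",
                        paste(odd, collapse = ", ")),
                "relmat_base_warning")
  }
  i <- pos[paired & pos < partner]
  arcs <- cbind(i, partner[i])
  arc_diagram(n, arcs, paste(base, collapse = ""))
}

#' Write an arc diagram as Bpseq text
#'
#' Emits canonical three-column Bpseq for positions 1..length.  Diagrams
#' with an empty sequence (abstractions) are written with 'N' residues.
#' `parse_bpseq(write_bpseq(d))` reproduces `d` whenever `d` contains no
#' contiguous arcs (abstractions may; Bpseq encodes real structures).
#'
#' @param diagram An [arc_diagram()].
#' @param path Optional file path; when given, the text is also written
#'   there.
#' @return The Bpseq text as a single string (invisibly when `path` is
#'   given).
#' @export
write_bpseq <- function(diagram, path = NULL) {
  stopifnot(is_arc_diagram(diagram))
  n <- diagram$length
  partner <- integer(n)
  if (nrow(diagram$arcs) > 0) {
    partner[diagram$arcs[, 1]] <- diagram$arcs[, 2]
    partner[diagram$arcs[, 2]] <- diagram$arcs[, 1]
  }
  base <- if (nzchar(diagram$sequence)) {
    strsplit(diagram$sequence, "")[[1]]
  } else {
    rep("N", n)
  }
  txt <- paste0(paste(seq_len(n), base, partner), collapse = "\n")
  if (n > 0) txt <- paste0(txt, "\n")
  if (!is.null(path)) {
    cat(txt, file = path)
    return(invisible(txt))
  }
  txt
}

#' Path to a bundled example file
#'
#' The package ships small fixtures: `pk28.bpseq` (a 28-residue
#' pseudoknotted structure), `duplex19.bpseq` (a 19-residue RNA-RNA duplex,
#' strand break at 9), `nineloop.bpseq` (a 28-residue, nine-loop structure with
#' placeholder residues), and the serialized relation matrices
#' `sixloop_structure.tsv` / `threeloop_pattern.tsv`.
#'
#' @param file File name; with no argument, lists the available files.
#' @return A file path, or a character vector of file names.
#' @export
relmat_example <- function(file = NULL) {
  if (is.null(file)) {
    return(list.files(system.file("extdata", package = "relmat")))
  }
  p <- system.file("extdata", file, package = "relmat")
  if (!nzchar(p)) stop_relmat(sprintf("no bundled file '%s'", file),
                              "relmat_usage_error")
  p
}
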