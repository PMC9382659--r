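# Seeded generators of valid arc diagrams, and a realizer turning a
# relation matrix back into a diagram.  All randomness is drawn inside a
# saved/restored RNG scope, so generation never perturbs the caller's
# random stream and a given seed always yields the same diagram.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the random diagram generator
#'
#' @param length Vertex count of the diagram (>= 2 * n_arcs).
#' @param n_arcs Number of arcs to place.
#' @param crossing_bias Probability in \[0, 1\] that each new arc attempts
#'   to cross an existing one.  0 guarantees a pseudoknot-free diagram;
#'   values near 1 produce dense pseudoknots.
#' @param seed Integer seed; the same configuration always generates the
#'   same diagram.
#' @return A `generator_config` list.
#' @export
generator_config <- function(length, n_arcs, crossing_bias = 0, seed = 1L) {
  length <- as.integer(length); n_arcs <- as.integer(n_arcs)
  if (is.na(length) || is.na(n_arcs) || n_arcs < 0 || length < 0 ||
      2L * n_arcs > length) {
    stop_relmat("infeasible generator config: need 2 * n_arcs <= length",
                "relmat_infeasible_config")
  }
  if (!is.numeric(crossing_bias) || crossing_bias < 0 || crossing_bias > 1) {
    stop_relmat("crossing_bias must lie in [0, 1]", "relmat_infeasible_config")
  }
  structure(list(length = length, n_arcs = n_arcs,
                 crossing_bias = crossing_bias, seed = as.integer(seed)),
            class = "generator_config")
}

# one construction attempt; NULL when it paints itself into a corner
try_build_arcs <- function(L, K, bias) {
  free <- rep(TRUE, L)
  arcs <- matrix(integer(), 0, 2)
  for (k in seq_len(K)) {
    placed <- FALSE
    if (nrow(arcs) > 0 && stats::runif(1) < bias) {
      # force a crossing with some existing arc (a, b): open inside, close after
      for (r in sample.int(nrow(arcs))) {
        a <- arcs[r, 1]; b <- arcs[r, 2]
        is_ <- which(free)[which(free) > a & which(free) < b]
        js_ <- which(free)[which(free) > b]
        if (length(is_) > 0 && length(js_) > 0) {
          i <- if (length(is_) == 1) is_ else sample(is_, 1)
          j <- if (length(js_) == 1) js_ else sample(js_, 1)
          arcs <- rbind(arcs, c(i, j)); free[c(i, j)] <- FALSE
          placed <- TRUE
          break
        }
      }
    }
    if (!placed) {
      # place an arc that crosses nothing (keeps bias = 0 pseudoknot-free)
      cand_i <- which(free)
      if (length(cand_i) > 1) cand_i <- sample(cand_i)
      for (i in cand_i) {
        cand <- which(free)
        cand <- cand[cand > i + 1L]
        if (nrow(arcs) > 0) {
          o <- arcs[, 1]; cl <- arcs[, 2]
          ok <- vapply(cand, function(j) {
            !any((o < i & i < cl & cl < j) | (i < o & o < j & j < cl))
          }, logical(1))
          cand <- cand[ok]
        }
        if (length(cand) > 0) {
          j <- if (length(cand) == 1) cand else sample(cand, 1)
          arcs <- rbind(arcs, c(i, j)); free[c(i, j)] <- FALSE
          placed <- TRUE
          break
        }
      }
    }
    if (!placed) return(NULL)
  }
  arcs
}

#' Generate a random valid arc diagram
#'
#' Arcs are placed one at a time on free positions.  With probability
#' `crossing_bias` a new arc is forced to cross a randomly chosen existing
#' arc (falling back to an unconstrained placement when impossible);
#' otherwise it is placed so that it crosses nothing.  With
#' `crossing_bias = 0` the output is therefore always pseudoknot-free.
#' Residues are sampled uniformly from A, C, G, U.
#'
#' @param config A [generator_config()].
#' @return A valid [arc_diagram()] with `n_arcs` arcs, none contiguous.
#' @examples
#' generate_diagram(generator_config(20, 5, crossing_bias = 1, seed = 7))
#' @export
generate_diagram <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    arcs <- NULL
    for (attempt in 1:64) {
      arcs <- try_build_arcs(config$length, config$n_arcs,
                             config$crossing_bias)
      if (!is.null(arcs)) break
    }
    if (is.null(arcs)) {
      stop_relmat(sprintf(
        "could not place %d arcs on %d positions with crossing_bias %.2f",
        config$n_arcs, config$length, config$crossing_bias),
        "relmat_infeasible_config")
    }
    seq <- paste(sample(c("A", "C", "G", "U"), config$length, replace = TRUE),
                 collapse = "")
    arc_diagram(config$length, arcs, seq)
  })
}

#' Realize a relation matrix as an arc diagram
#'
#' Searches for a diagram whose close-ordered loops reproduce the given
#' matrix exactly.  Because loop enumeration follows closing position, the
#' closing endpoints can be laid down append-only, and the relation of a
#' new loop to every earlier one depends only on where its opening
#' endpoint falls relative to that loop's endpoints: after the close
#' (concatenation), before the open (nesting), or between the two
#' (crossing).  The search therefore backtracks over endpoint orderings —
#' each earlier loop narrows the feasible insertion slots of the new open
#' to an interval — and finally assigns the smallest integer coordinates
#' consistent with the ordering (leaving one unpaired gap inside each
#' innermost arc so that no pair is contiguous).  The search is
#' exhaustive: an unrealizable matrix (e.g. L1 left of L2, L2 left of L3,
#' yet L1 nested in L3) fails with an explicit error rather than an
#' approximation.
#'
#' @param matrix A `relation_matrix` with N >= 1 loops.
#' @return An [arc_diagram()] with empty sequence whose
#'   `build_relation_matrix(enumerate_loops(.))` equals `matrix`.
#' @export
realize_matrix <- function(matrix) {
  stopifnot(inherits(matrix, "relation_matrix"))
  n <- matrix$n
  if (n < 1) {
    stop_relmat("cannot realize an empty matrix", "relmat_usage_error")
  }
  # endpoint ids: -s = open of loop s, +s = close of loop s
  search <- function(t, ids) {
    if (t > n) return(ids)
    lo <- 0L; hi <- length(ids)  # slot p = insert after p existing endpoints
    for (s in seq_len(t - 1L)) {
      po <- match(-s, ids); pc <- match(s, ids)
      sym <- matrix$mat[s, t]
      if (sym == "o") {              # open after close of L_s
        lo <- max(lo, pc)
      } else if (sym == "n") {       # open before open of L_s
        hi <- min(hi, po - 1L)
      } else {                       # crossing: open inside (o_s, c_s)
        lo <- max(lo, po); hi <- min(hi, pc - 1L)
      }
      if (lo > hi) return(NULL)
    }
    for (p in lo:hi) {
      cand <- c(append(ids, -t, after = p), t)  # close always appended last
      res <- search(t + 1L, cand)
      if (!is.null(res)) return(res)
    }
    NULL
  }
  ids <- search(2L, c(-1L, 1L))
  if (is.null(ids)) {
    stop_relmat("matrix is not realizable by any arc diagram",
                "relmat_unrealizable_matrix")
  }
  # compact coordinates: consecutive integers, +2 when an open directly
  # precedes its own close (keeps every pair non-contiguous)
  pos <- integer(length(ids))
  pos[1] <- 1L
  for (k in 2:length(ids)) {
    gap <- if (ids[k - 1] == -ids[k] && ids[k] > 0) 2L else 1L
    pos[k] <- pos[k - 1] + gap
  }
  arcs <- cbind(pos[match(-seq_len(n), ids)], pos[match(seq_len(n), ids)])
  arc_diagram(max(pos), arcs)
}
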