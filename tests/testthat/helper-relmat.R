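# Shared fixtures and property-check helpers.  The worked-example arc sets
# are rebuilt in code so every test states its input explicitly.

pk28_arcs <- function() {
  rbind(c(1, 7), c(2, 6), c(8, 11), c(12, 24), c(13, 23), c(14, 17),
        c(18, 27), c(19, 22))
}

duplex19_arcs <- function() {
  rbind(c(2, 8), c(3, 7), c(4, 15), c(5, 14), c(10, 18), c(11, 17),
        c(12, 16))
}

nineloop_arcs <- function() {
  rbind(c(2, 6), c(4, 11), c(8, 13), c(10, 18), c(16, 19), c(15, 20),
        c(9, 24), c(22, 27), c(21, 28))
}

pk28_diagram <- function() {
  arc_diagram(28, pk28_arcs(), "GAUGUGUCAUCAGACCUGCACGCUAGUU")
}

duplex19_diagram <- function() {
  arc_diagram(19, duplex19_arcs(), "CAGCCUCUGAUGUGUCAUC")
}

nineloop_diagram <- function() arc_diagram(28, nineloop_arcs())

sixloop_structure <- function() {
  deserialize_matrix(relmat_example("sixloop_structure.tsv"))
}

threeloop_pattern <- function() {
  deserialize_matrix(relmat_example("threeloop_pattern.tsv"))
}

arcs_set <- function(d) {
  a <- d$arcs
  sort(paste0("(", a[, 1], ",", a[, 2], ")"))
}

# deterministic family of generated diagrams covering nested and
# pseudoknotted regimes
generated_diagrams <- function(k, seed0 = 1000L) {
  lapply(seq_len(k), function(i) {
    len <- 10L + (i * 7L) %% 31L
    arcs <- max(1L, (len %/% 3L) - (i %% 3L))
    bias <- c(0, 0.3, 0.7, 1)[1L + (i %% 4L)]
    generate_diagram(generator_config(len, arcs, bias, seed = seed0 + i))
  })
}

# random (not necessarily realizable) relation matrix of n loops
random_relation_matrix <- function(n) {
  mat <- matrix(NA_character_, n, n)
  if (n >= 2) {
    ut <- upper.tri(mat)
    mat[ut] <- sample(c("o", "n", "x"), sum(ut), replace = TRUE)
  }
  relmat:::new_relation_matrix(n, mat)
}

window_matrix <- function(m, s, width) {
  sub <- m$mat[s:(s + width - 1L), s:(s + width - 1L), drop = FALSE]
  keep <- matrix(NA_character_, width, width)
  keep[upper.tri(keep)] <- sub[upper.tri(sub)]
  relmat:::new_relation_matrix(width, keep)
}

# --- property checks shared between unit and acceptance suites ---------

# exactly one relation predicate holds for each of n random loop pairs;
# returns the number of violations
trichotomy_violations <- function(n_pairs) {
  bad <- 0L
  pts <- replicate(n_pairs, sort(sample.int(200L, 4L)), simplify = FALSE)
  for (p in pts) {
    # all three pairings of 4 ordered points into two loops (a closes first)
    pairings <- list(list(c(p[1], p[2]), c(p[3], p[4])),
                     list(c(p[2], p[3]), c(p[1], p[4])),
                     list(c(p[1], p[3]), c(p[2], p[4])))
    for (lp in pairings) {
      a <- lp[[1]]; b <- lp[[2]]
      concat <- a[2] < b[1]
      nest <- b[1] < a[1] && a[1] < a[2] && a[2] < b[2]
      cross <- a[1] < b[1] && b[1] < a[2] && a[2] < b[2]
      if (sum(concat, nest, cross) != 1L) bad <- bad + 1L
      sym <- classify_relation(a, b)
      expected <- if (concat) "o" else if (nest) "n" else "x"
      if (sym != expected) bad <- bad + 1L
    }
  }
  bad
}

# relation matrix of the core == original matrix restricted to the
# stack-representative loops
core_restriction_holds <- function(d) {
  loops <- enumerate_loops(d)
  full <- build_relation_matrix(loops)
  reps <- relmat:::collapse_deleted(d$arcs)$sources
  rep_idx <- sort(match(paste(reps[, 1], reps[, 2]),
                        paste(loops$open, loops$close)))
  core_m <- build_relation_matrix(enumerate_loops(core_of(d)))
  restricted <- full$mat[rep_idx, rep_idx, drop = FALSE]
  identical(restricted[upper.tri(restricted)],
            core_m$mat[upper.tri(core_m$mat)])
}

# number of disagreements between matcher and oracle over n random
# target/pattern matrix pairs (half with the pattern planted)
oracle_disagreements <- function(n_cases, n_max = 40L, m_max = 8L) {
  bad <- 0L
  for (i in seq_len(n_cases)) {
    n <- sample.int(n_max, 1)
    m <- sample.int(min(m_max, max(1L, n)), 1)
    target <- random_relation_matrix(n)
    pattern <- if (i %% 2L == 0L && n >= m) {
      window_matrix(target, sample.int(n - m + 1L, 1), m)
    } else {
      random_relation_matrix(m)
    }
    a <- match_pattern(target, pattern)
    b <- brute_force_match(target, pattern)
    if (!identical(a$starts, b$starts)) bad <- bad + 1L
    if (i %% 2L == 0L && n >= m && length(b$starts) < 1L) bad <- bad + 1L
  }
  bad
}

# realize-then-rebuild round trips for n random small matrices taken from
# generated diagrams (guaranteed realizable); returns failures
realize_roundtrip_failures <- function(n_cases, seed0 = 5000L) {
  bad <- 0L
  for (i in seq_len(n_cases)) {
    k <- 1L + (i %% 8L)
    d <- generate_diagram(generator_config(4L * k + 4L, k,
                                           c(0, 0.5, 1)[1L + (i %% 3L)],
                                           seed = seed0 + i))
    m <- build_relation_matrix(enumerate_loops(d))
    r <- realize_matrix(m)
    m2 <- build_relation_matrix(enumerate_loops(r))
    if (!identical(m$mat, m2$mat)) bad <- bad + 1L
  }
  bad
}
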