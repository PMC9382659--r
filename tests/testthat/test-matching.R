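test_that("the worked three-loop pattern occurs twice in the six-loop structure", {
  res <- match_pattern(sixloop_structure(), threeloop_pattern())
  expect_identical(res$starts, c(1L, 4L))
  expect_identical(as.data.frame(res)$loops, c("1,2,3", "4,5,6"))
})

test_that("degenerate pattern sizes behave per contract", {
  tgt <- sixloop_structure()
  expect_identical(match_pattern(tgt, tgt)$starts, 1L)  # identity
  one <- relmat:::new_relation_matrix(1L, matrix(NA_character_, 1, 1))
  expect_identical(match_pattern(tgt, one)$starts, 1:6)  # M = 1
  big <- random_relation_matrix(9)
  expect_identical(match_pattern(threeloop_pattern(), big)$starts, integer(0))
  empty <- relmat:::new_relation_matrix(0L, matrix(NA_character_, 0, 0))
  expect_error(match_pattern(tgt, empty), class = "relmat_usage_error")
  expect_error(brute_force_match(tgt, empty), class = "relmat_usage_error")
})

test_that("matcher and brute-force oracle agree on random instances", {
  set.seed(7)
  expect_identical(oracle_disagreements(150), 0L)
})

test_that("occurrence count is bounded by N - M + 1, with equality for periodic targets", {
  periodic <- relmat:::new_relation_matrix(10L, {
    m <- matrix(NA_character_, 10, 10); m[upper.tri(m)] <- "o"; m
  })
  pat <- relmat:::new_relation_matrix(3L, {
    m <- matrix(NA_character_, 3, 3); m[upper.tri(m)] <- "o"; m
  })
  res <- match_pattern(periodic, pat)
  expect_identical(res$starts, 1:8)
  set.seed(11)
  for (i in 1:20) {
    tgt <- random_relation_matrix(sample(5:25, 1))
    p <- random_relation_matrix(sample(2:4, 1))
    expect_lte(length(match_pattern(tgt, p)$starts),
               tgt$n - p$n + 1L)
  }
})

test_that("every structure matches itself exactly once at structure level", {
  for (d in generated_diagrams(20)) {
    res <- match_structures(d, d, level = "structure")
    expect_identical(res$starts, 1L)
  }
})

test_that("match_structures abstracts both sides and annotates RRI classes", {
  tgt <- realize_matrix(sixloop_structure())
  pat <- realize_matrix(threeloop_pattern())
  res <- match_structures(tgt, pat)
  expect_identical(res$starts, c(1L, 4L))
  # pattern supplied as a matrix bypasses abstraction
  res2 <- match_structures(tgt, threeloop_pattern())
  expect_identical(res2$starts, c(1L, 4L))
  # shadow-level matching on the interaction duplex finds itself
  fb <- duplex19_diagram()
  res3 <- match_structures(fb, fb, level = "shadow")
  expect_identical(res3$starts, 1L)
  # pseudoknot-free pattern has an empty shadow -> usage error
  pkfree <- arc_diagram(10, list(c(1, 5), c(2, 4)))
  expect_error(match_structures(fb, pkfree, level = "shadow"),
               class = "relmat_usage_error")
  # strand-break annotation carries loop classes onto occurrences
  res4 <- match_structures(fb, fb, strand_break = 9)
  expect_identical(res4$classes[[1]],
                   c("INTRA1", "INTRA1", "INTER", "INTER",
                     "INTRA2", "INTRA2", "INTRA2"))
  # core-level loops inherit the class of their representative arc
  res5 <- match_structures(fb, fb, level = "core", strand_break = 9)
  expect_identical(res5$loop_classes, c("INTRA1", "INTER", "INTRA2"))
})

test_that("comparison work grows at most quadratically with target size", {
  set.seed(99)
  pat <- random_relation_matrix(4)
  work <- vapply(c(50L, 100L, 200L, 400L), function(n) {
    tgt <- random_relation_matrix(n)
    attr(match_pattern(tgt, pat, count_comparisons = TRUE), "comparisons")
  }, integer(1))
  expect_lte(work[4] / work[1], (400 / 50)^2)
  expect_true(all(diff(work) > 0))
})
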