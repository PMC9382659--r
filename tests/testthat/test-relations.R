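test_that("classify_relation reproduces the worked loop relations", {
  expect_identical(classify_relation(c(2, 6), c(4, 11)), "x")
  expect_identical(classify_relation(c(2, 6), c(8, 13)), "o")
  expect_identical(classify_relation(c(22, 27), c(21, 28)), "n")
  expect_identical(classify_relation(c(1, 3), c(4, 6)), "o")
  expect_error(classify_relation(c(4, 11), c(2, 6)),
               class = "relmat_relation_error")
  expect_error(classify_relation(c(2, 6), c(6, 9)),
               class = "relmat_relation_error")
})

test_that("exactly one relation holds for random loop pairs", {
  set.seed(42)
  expect_identical(trichotomy_violations(500), 0L)
})

test_that("the relation matrix has N(N-1)/2 entries filled from coordinates", {
  m <- build_relation_matrix(enumerate_loops(nineloop_diagram()))
  expect_identical(m$n, 9L)
  expect_identical(sum(!is.na(m$mat)), 36L)
  # mutually consistent worked entries
  expect_identical(m$mat[1, 2], "x")
  expect_identical(m$mat[1, 3], "o")
  expect_identical(m$mat[8, 9], "n")
  expect_identical(m$mat[2, 6], "o")

  m1a <- build_relation_matrix(enumerate_loops(pk28_diagram()))
  crosses <- which(m1a$mat == "x", arr.ind = TRUE)
  expect_identical(nrow(crosses), 2L)  # (13,23)x(18,27) and (12,24)x(18,27)
  expect_setequal(paste(crosses[, 1], crosses[, 2]), c("6 8", "7 8"))

  single <- build_relation_matrix(data.frame(index = 1L, open = 1L,
                                             close = 5L))
  expect_identical(single$n, 1L)
  expect_identical(sum(!is.na(single$mat)), 0L)
})

test_that("a pseudoknot-free diagram's matrix contains no crossing symbol", {
  for (i in 1:10) {
    d <- generate_diagram(generator_config(30, 8, 0, seed = 300 + i))
    m <- build_relation_matrix(enumerate_loops(d))
    expect_false(any(m$mat == "x", na.rm = TRUE))
  }
})

test_that("core matrices are restrictions of the original matrix", {
  expect_true(core_restriction_holds(pk28_diagram()))
  expect_true(core_restriction_holds(nineloop_diagram()))
  for (d in generated_diagrams(30)) {
    expect_true(core_restriction_holds(d))
  }
})

test_that("serialization round-trips and rejects tampered input", {
  pat <- threeloop_pattern()
  txt <- serialize_matrix(pat)
  expect_identical(strsplit(txt, "\n")[[1]],
                   c("N 3", "1\t2\tx", "1\t3\tx", "2\t3\tn"))
  expect_identical(deserialize_matrix(txt), pat)
  expect_identical(serialize_matrix(relmat:::new_relation_matrix(
    1L, matrix(NA_character_, 1, 1))), "N 1\n")
  expect_error(deserialize_matrix("N 3\n1 2 x\n2 2 o\n2 3 n"),
               class = "relmat_matrix_format")
  expect_error(deserialize_matrix("N 3\n1 2 x\n1 3 x"),
               class = "relmat_matrix_format")
  expect_error(deserialize_matrix("N 3\n1 2 x\n1 3 q\n2 3 n"),
               class = "relmat_matrix_format")
  expect_error(deserialize_matrix("N 3\n1 2 x\n1 3 x\n1 3 n"),
               class = "relmat_matrix_format")
  for (d in generated_diagrams(15)) {
    m <- build_relation_matrix(enumerate_loops(d))
    expect_identical(deserialize_matrix(serialize_matrix(m))$mat, m$mat)
  }
})

test_that("RRI permutation orders blocks INTRA1, INTER, INTRA2 and keeps entries", {
  d <- duplex19_diagram()
  ann <- annotate_rri(d, 9)
  m <- build_relation_matrix(enumerate_loops(d))
  pm <- permute_rri_matrix(m, ann)
  expect_identical(unname(attr(pm, "blocks")), c(2L, 2L, 3L))
  # entries travel with their loop pair
  lab <- pm$labels
  for (p in 1:(pm$n - 1)) {
    for (q in (p + 1):pm$n) {
      a <- lab[p]; b <- lab[q]
      expect_identical(pm$mat[p, q], m$mat[min(a, b), max(a, b)])
    }
  }
  # all-INTRA1 annotation -> identity permutation
  id <- permute_rri_matrix(m, rep("INTRA1", m$n))
  expect_identical(id$mat, m$mat)
  expect_identical(id$labels, m$labels)
  # applying the permutation again (classes now block-sorted) is stable
  sorted_classes <- ann$loops$class[order(match(ann$loops$class,
                                          c("INTRA1", "INTER", "INTRA2")))]
  pm2 <- permute_rri_matrix(pm, sorted_classes)
  expect_identical(pm2$mat, pm$mat)
  # explicit non-trivial permutation on a 3-loop matrix
  p3 <- permute_rri_matrix(threeloop_pattern(), c("INTRA2", "INTRA1", "INTER"))
  expect_identical(p3$labels, c(2L, 3L, 1L))
  expect_identical(p3$mat[1, 2], "n")
  expect_identical(p3$mat[1, 3], "x")
  expect_identical(p3$mat[2, 3], "x")
})
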