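test_that("uniform DP reproduces the worked toy networks", {
  tb <- compute_uniform_tables("GGGGCCC")
  expect_identical(uniform_Z(tb), 8)
  expect_identical(uniform_Q(tb, "MS2"), 32)
  expect_identical(uniform_expected_degree(tb, "MS2")$degree, 4)

  tb12 <- compute_uniform_tables("ACGUACGUACGU")
  expect_identical(uniform_Z(tb12), 35)
  expect_identical(uniform_Q(tb12, "MS1"), 126)
  expect_identical(uniform_Q(tb12, "SHIFT_ONLY"), 68)
  expect_identical(uniform_Q(tb12, "MS2"), 194)
  expect_equal(uniform_expected_degree(tb12, "MS1")$degree, 3.6)
  expect_equal(uniform_expected_degree(tb12, "MS2")$degree, 194 / 35)
})

test_that("single-structure sequences give zero moves and trivial tables", {
  tb <- compute_uniform_tables("AAAA")
  expect_identical(uniform_Z(tb), 1)
  for (ms in c("MS1", "MS2", "SHIFT_ONLY")) {
    r <- uniform_expected_degree(tb, ms)
    expect_identical(c(r$Q, r$Z, r$degree, r$normalized_degree), c(0, 1, 0, 0))
  }
  # all four A's are visible and pairable with U; with any other nucleotide
  # class nothing is pairable
  expect_identical(tb$F[1, 4 + 1, 4, 4 + 1], 1)       # c = U, x = 4
  expect_identical(sum(tb$F[1, 4 + 1, 4, -(4 + 1)]), 0)
  expect_identical(tb$F[1, 4 + 1, 1, 0 + 1], 1)       # c = A, x = 0
  expect_true(all(tb$EL[1, 4 + 1, ] == 0))
})

test_that("uniform DP equals the enumeration oracle on random sequences", {
  set.seed(20240917)
  rule <- pairing_rule()
  for (t in 1:40) {
    s <- rand_rna(sample(5:13, 1))
    tb <- compute_uniform_tables(s)
    expect_identical(uniform_Z(tb), as.numeric(length(enumerate_structures(s, rule))))
    for (ms in c("MS1", "MS2", "SHIFT_ONLY")) {
      expect_identical(uniform_Q(tb, ms), as.numeric(oracle_Q(s, ms, rule)$Q),
                       label = paste(s, ms))
    }
    expect_identical(uniform_Q(tb, "MS1") + uniform_Q(tb, "SHIFT_ONLY"),
                     uniform_Q(tb, "MS2"))
  }
})

test_that("F and G partition every interval ensemble", {
  set.seed(5)
  for (t in 1:6) {
    s <- rand_rna(sample(8:12, 1))
    tb <- compute_uniform_tables(s)
    n <- nchar(s)
    for (cc in 1:4) for (i in 1:n) for (j in i:n) {
      expect_equal(sum(tb$F[i, j + 1, cc, ]), tb$Z[i, j + 1])
      if (j - i > 3) expect_equal(sum(tb$G[i, j + 1, cc, ]), tb$Z[i, j])
    }
  }
})

test_that("with an all-pairs predicate the interval DP matches the homopolymer model", {
  for (theta in c(1L, 3L)) {
    rule <- pairing_rule("homopolymer", theta)
    hp <- homopolymer_tables(12L, theta = theta, representation = "exact")
    for (n in c(6L, 9L, 12L)) {
      tb <- compute_uniform_tables(strrep("A", n), rule)
      expect_identical(uniform_Z(tb), hp$Z[n + 1L])
      expect_identical(uniform_Q(tb, "MS1"), hp$Q_ms1[n + 1L])
      expect_identical(uniform_Q(tb, "MS2"), hp$Q_ms2[n + 1L])
    }
  }
})
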