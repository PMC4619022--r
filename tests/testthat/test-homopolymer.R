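test_that("homopolymer tables match exhaustive enumeration for small n", {
  for (theta in c(1L, 3L)) {
    tb <- homopolymer_tables(12L, theta = theta, representation = "exact")
    for (n in 0:12) {
      or <- homopolymer_oracle(n, theta)
      expect_identical(tb$Z[n + 1L], as.numeric(or$Z))
      expect_identical(tb$E[n + 1L], as.numeric(or$E))
      expect_identical(tb$Q_ms1[n + 1L], as.numeric(or$Q_ms1))
      expect_identical(tb$Q_ms2[n + 1L], as.numeric(or$Q_ms2))
      expect_identical(tb$Q_shift[n + 1L], as.numeric(or$Q_ms2 - or$Q_ms1))
      for (x in names(or$f)) {
        expect_identical(tb$f[n + 1L, as.integer(x) + 1L],
                         as.numeric(or$f[[x]]))
      }
    }
  }
})

test_that("known small counts hold (Z4, Z5, E3, Q3, degenerate lengths)", {
  tb <- homopolymer_tables(10L, representation = "exact")
  expect_identical(tb$Z[4 + 1], 4)   # empty, (1,3), (1,4), (2,4)
  expect_identical(tb$Z[5 + 1], 8)
  expect_identical(tb$E[3 + 1], 1)   # only {(1,3)} has an external pair
  expect_identical(tb$Q_ms2[3 + 1], 2)
  expect_identical(tb$Q_ms2[1 + 1], 0)
  expect_identical(tb$Q_ms2[2 + 1], 0)
  expect_identical(normalized_degree(tb, "MS2", 3), 1 / 3)
  expect_error(homopolymer_tables(-1), class = "rnanetdeg_negative_length")
  expect_error(normalized_degree(tb, "MS2", 11),
               class = "rnanetdeg_index_out_of_range")
})

test_that("f and g partition the ensemble (row sums give Z)", {
  tb <- homopolymer_tables(14L, representation = "exact")
  for (n in 0:14) {
    expect_equal(sum(tb$f[n + 1L, ]), tb$Z[n + 1L])
    if (n > 2L) expect_equal(sum(tb$g[n + 1L, ]), tb$Z[n])  # position n unpaired
  }
})

test_that("exact and rescaled representations agree to 10 significant digits", {
  the <- homopolymer_tables(36L, representation = "exact")
  ths <- homopolymer_tables(36L, representation = "scaled")
  expect_equal(ths$representation, "scaled")
  for (ms in c("MS1", "MS2")) {
    a <- normalized_degree(the, ms, 3:36)
    b <- normalized_degree(ths, ms, 3:36)
    expect_lt(max(abs(a - b) / a), 1e-10)
  }
  # scaled tables are internally stable: prefixes of a longer run agree
  big <- homopolymer_tables(320L, representation = "scaled")
  mid <- homopolymer_tables(300L, representation = "scaled")
  expect_lt(max(abs(normalized_degree(big, "MS2", 10:300) -
                    normalized_degree(mid, "MS2", 10:300))), 1e-10)
})

test_that("MS1 + SHIFT_ONLY = MS2 along the whole table", {
  tb <- homopolymer_tables(200L, representation = "scaled")
  q <- homopolymer_Q(tb, "MS1") + homopolymer_Q(tb, "SHIFT_ONLY")
  expect_equal(as.numeric(q), as.numeric(homopolymer_Q(tb, "MS2")),
               tolerance = 1e-12)
})

test_that("theta = 3 normalized MS1 degree converges toward the analytic constant", {
  tb <- homopolymer_tables(600L, theta = 3L, representation = "scaled")
  limit <- 0.4734176431521986
  dev <- abs(normalized_degree(tb, "MS1", c(150, 300, 600)) - limit)
  expect_true(all(diff(dev) < 0))              # deviation shrinks with n
  expect_lt(dev[3], 2e-3)
  # shifts multiply the neighbourhood: MS2/MS1 ratio well above 3
  expect_gt(normalized_degree(tb, "MS2", 600) /
              normalized_degree(tb, "MS1", 600), 3)
})
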