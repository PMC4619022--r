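test_that("arc accessors agree with direct set enumeration", {
  set.seed(31)
  rule <- pairing_rule()
  for (t in 1:5) {
    s <- rand_rna(sample(8:14, 1), gc = 0.6)
    n <- nchar(s)
    arcs <- arc_counts(s, rule)
    seqp <- parse_sequence(s)
    for (rep in 1:20) {
      ij <- sort(sample(n, 2))
      i <- ij[1]; j <- ij[2]
      expect_identical(arcs$arc1a(i, j), direct_arc1a(s, i, j, rule))
      # arc1b / arc1c by direct filtering
      d1b <- sum(vapply((i + 1):max(i + 1, j - 1), function(k)
        k > i + 3 && k < j && can_pair(seqp, i, k, rule), TRUE))
      expect_identical(arcs$arc1b(i, j), as.integer(d1b))
      d1c <- sum(vapply(i:(j - 1), function(k)
        k > i && k < j - 3 && can_pair(seqp, k, j, rule), TRUE))
      expect_identical(arcs$arc1c(i, j), as.integer(d1c))
    }
    # definitional identity of arc3 on random interior-loop tuples
    for (rep in 1:10) {
      v <- sort(sample(n, 4))
      i <- v[1]; l <- v[2]; r <- v[3]; j <- v[4]
      expect_identical(arcs$arc3(i, j, l, r),
                       arcs$arc1a(i + 1, l - 1) + arcs$arc1a(r + 1, j - 1) +
                         arcs$arc2(i, j, l, r))
    }
  }
  expect_identical(arc_counts("AAAA")$arc1a(1, 4), 0L)
})

test_that("zero-energy model reduces exactly to the uniform counting model", {
  pz <- turner_parameters("zero")
  for (s in c("GGGGCCC", "ACGUACGUACGU", "AAAA")) {
    pf <- mccaskill_partition(s, pz)
    expect_equal(pf$Z[1, nchar(s) + 1], uniform_Z(compute_uniform_tables(s)))
  }
  # multiloop-free: all Q agree exactly with the counting model
  expect_equal(turner_Q("GGGGCCC", pz, "MS2")$Q, 32)
  expect_equal(turner_expected_degree("GGGGCCC", pz, "MS2")$degree, 4)
  expect_equal(turner_expected_degree("GGGGCCC", pz, "MS1")$degree, 2)
  expect_equal(turner_Q("ACGUACGUACGU", pz, "MS2")$Q, 194)
  # in general the restricted count can only drop moves
  set.seed(77)
  for (t in 1:6) {
    s <- rand_rna(sample(12:16, 1), gc = 0.7)
    expect_lte(turner_Q(s, pz, "MS2")$Q, uniform_Q(s, "MS2") + 1e-9)
    expect_gte(turner_Q(s, pz, "MS2")$Q, turner_Q(s, pz, "MS1")$Q - 1e-9)
  }
})

test_that("partition function matches the enumerated Boltzmann sum", {
  p <- turner_parameters("builtin_minimal")
  rule <- pairing_rule()
  expect_equal(mccaskill_partition("AAAA", p)$Z[1, 5], 1)
  set.seed(41)
  for (t in 1:10) {
    s <- rand_rna(sample(8:14, 1), gc = 0.55)
    pf <- mccaskill_partition(s, p)
    zo <- oracle_Q(s, "MS2", rule, params = p)$Z
    expect_lt(abs(pf$Z[1, nchar(s) + 1] - zo) / zo, 1e-9)
  }
})

test_that("Boltzmann Q equals the restricted enumeration oracle", {
  p <- turner_parameters("builtin_minimal")
  rule <- pairing_rule()
  set.seed(52)
  for (t in 1:10) {
    s <- rand_rna(sample(8:14, 1), gc = 0.55)
    for (ms in c("MS1", "MS2")) {
      dp <- turner_Q(s, p, ms)$Q
      or <- oracle_Q(s, ms, rule, restricted = TRUE, params = p)$Q
      expect_lt(abs(dp - or) / max(1e-12, or), 1e-9, label = paste(s, ms))
    }
    expect_equal(turner_Q(s, p, "SHIFT_ONLY")$Q,
                 turner_Q(s, p, "MS2")$Q - turner_Q(s, p, "MS1")$Q)
  }
})

test_that("restricted multiloop move taxonomy is exact at uniform weights", {
  # zero energies give every structure full weight, so any taxonomy
  # disagreement shows as an integer difference
  pz <- turner_parameters("zero")
  rule <- pairing_rule()
  set.seed(63)
  for (t in 1:5) {
    s <- rand_rna(sample(14:16, 1), gc = 0.7)
    for (ms in c("MS1", "MS2")) {
      expect_equal(turner_Q(s, pz, ms)$Q,
                   oracle_Q(s, ms, rule, restricted = TRUE)$Q,
                   label = paste(s, ms))
    }
  }
})

test_that("as temperature grows the Boltzmann degree approaches the uniform limit", {
  s <- "GCAGCGGAUCCG"
  hot <- turner_parameters("builtin_minimal", temperature = 1e7, max_loop = Inf)
  cold0 <- turner_parameters("zero")
  expect_equal(turner_expected_degree(s, hot, "MS2")$degree,
               turner_expected_degree(s, cold0, "MS2")$degree,
               tolerance = 1e-4)
})
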