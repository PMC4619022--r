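test_that("degree distributions have the right means, support and spread", {
  dd <- degree_distribution("GGGGCCC", "B", "MS2")
  expect_identical(dd$mean, 4)
  expect_equal(sum(dd$histogram$weight), 1)
  expect_identical(dd$coverage, 1)

  dd1 <- degree_distribution("GGGGCCC", "B", "MS1")
  expect_identical(dd1$mean, 2)
  expect_true(all(dd1$histogram$degree %in% 1:6))

  single <- degree_distribution("AAAA", "B", "MS2")
  expect_identical(single$histogram$degree, 0L)
  expect_identical(single$histogram$weight, 1)
  expect_identical(single$sd, 0)
})

test_that("distribution mean equals the dynamic-programming expected degree", {
  set.seed(88)
  p <- turner_parameters("builtin_minimal")
  rule <- pairing_rule()
  for (t in 1:6) {
    s <- rand_rna(sample(6:12, 1))
    for (ms in c("MS1", "MS2")) {
      dd <- degree_distribution(s, "B", ms)
      expect_lt(abs(dd$mean - uniform_expected_degree(s, ms)$degree) /
                  max(1e-12, dd$mean + 1e-12), 1e-12)
      # Boltzmann model: the DP mean uses the restricted counter
      or <- oracle_Q(s, ms, rule, restricted = TRUE, params = p)
      expect_lt(abs(turner_expected_degree(s, p, ms)$degree - or$Q / or$Z),
                1e-9)
    }
  }
})

test_that("energy-cutoff coverage is monotone and reaches 1", {
  s <- "GGCGCAAGCGCC"
  p <- turner_parameters("builtin_minimal")
  cuts <- c(0.5, 2, 5, 100)
  cov <- vapply(cuts, function(ct)
    degree_distribution(s, "C", "MS2", p, energy_cutoff = ct)$coverage, 0)
  expect_true(all(diff(cov) >= -1e-12))
  expect_equal(cov[length(cov)], 1)
  expect_true(all(cov > 0 & cov <= 1))
  expect_error(degree_distribution(s, "B", "MS2", energy_cutoff = 1),
               class = "rnanetdeg_bad_argument")
})

test_that("contact order follows the direct formula", {
  co <- contact_order(validate_structure("GGGGCCC", rbind(c(1, 7), c(2, 6))))
  expect_equal(co$absolute, 5)
  expect_equal(co$relative, 5 / 7)
  one <- contact_order(rbind(c(3, 9)), n = 12)
  expect_equal(one$absolute, 6)
  expect_error(contact_order(validate_structure("GGGGCCC", NULL)),
               class = "rnanetdeg_empty_structure")
  # golden value for the 102-nt Y RNA reference structure
  y <- yrna_example()
  st <- validate_structure(y$sequence, parse_dot_bracket(y$dot_bracket),
                           pairing_rule("homopolymer", 3L))
  coy <- contact_order(st)
  expect_equal(coy$absolute, mean(st$pairs[, 2] - st$pairs[, 1]))
  expect_equal(round(coy$absolute, 4), 66.7391)  # 1535/23
  expect_true(coy$relative > 0 && coy$relative < 1)
})

test_that("expected native contacts are enumeration pair probabilities", {
  s0 <- rbind(c(1, 7), c(2, 6))
  r <- expected_native_contacts("GGGGCCC", s0, "B")
  expect_equal(r$expected_native_contacts, 0.5)  # each pair in 2 of 8 structures
  expect_equal(r$pair_probabilities$probability, c(2 / 8, 2 / 8))
  expect_identical(
    expected_native_contacts("GGGGCCC", NULL, "B")$expected_native_contacts, 0)
  # zero-energy Boltzmann weighting equals the uniform value
  rz <- expected_native_contacts("GGGGCCC", s0, "C", turner_parameters("zero"))
  expect_equal(rz$expected_native_contacts, r$expected_native_contacts)
  expect_lte(r$expected_native_contacts, nrow(s0))
})

test_that("conformational entropy is -sum p log p", {
  expect_equal(conformational_entropy("GGGGCCC", "B"), log(8))
  expect_identical(conformational_entropy("AAAA", "B"), 0)
  p <- turner_parameters("builtin_minimal")
  s <- "GGCGCAAGCGCC"
  nodes <- enumerate_structures(s)
  w <- vapply(nodes, function(x) exp(-energy_of_structure(s, x, p)$total / p$rt), 0)
  pr <- w / sum(w)
  expect_equal(conformational_entropy(s, "C", p), -sum(pr * log(pr)))
})

test_that("the metric table and correlation matrix assemble", {
  tab <- data.frame(
    id = c("a", "b", "c"),
    sequence = c("GGGGCCC", "ACGUACGUACGU", "GGCGCAAGCGCC"),
    dot_bracket = c("((...))", "((....))....", "((((....))))"))
  mt <- structure_metrics(tab)
  expect_equal(nrow(mt), 3L)
  expect_equal(mt$degree_ms2[1], 4)
  cm <- metric_correlations(mt)
  expect_true(all(abs(diag(cm)) - 1 < 1e-12))
  expect_equal(rownames(cm), colnames(cm))
})
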