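test_that("sequence parsing normalizes case, DNA letters and FASTA headers", {
  expect_equal(parse_sequence("GGGGCCC")$string, "GGGGCCC")
  expect_equal(parse_sequence("acgt")$string, "ACGU")
  expect_equal(parse_sequence(">hdr\nac\ngu")$string, "ACGU")
  err <- tryCatch(parse_sequence("ACGX"), condition = identity)
  expect_s3_class(err, "rnanetdeg_illegal_symbol")
  expect_equal(err$position, 4L)
  expect_error(parse_sequence("  \n"), class = "rnanetdeg_empty_input")
})

test_that("pairing predicate honours nucleotide identity and theta", {
  expect_true(can_pair("GGGGCCC", 1, 5))          # G.C, separation 4
  expect_false(can_pair("GGGGCCC", 1, 4))         # separation 3 <= theta
  expect_false(can_pair("GGGGCCC", 1, 2))
  expect_true(can_pair("AAAA", 1, 3, pairing_rule("homopolymer")))
  expect_error(can_pair("GGGGCCC", 5, 3), class = "rnanetdeg_index_out_of_range")
  expect_false(can_pair("AAAAAA", 1, 6))          # A.A never pairs (WC rule)
})

test_that("structure validation names the violated condition", {
  s <- validate_structure("GGGGCCC", rbind(c(1, 7), c(2, 6)))
  expect_s3_class(s, "secondary_structure")
  expect_equal(nrow(s$pairs), 2L)
  expect_error(validate_structure("GGGGCCC", rbind(c(1, 7), c(1, 6))),
               class = "rnanetdeg_base_triple")
  expect_error(validate_structure("GGGGCCC", rbind(c(1, 4))),
               class = "rnanetdeg_steric_violation")
  expect_error(validate_structure("GGGGGGG", rbind(c(1, 7))),
               class = "rnanetdeg_not_a_pair")
  expect_error(
    validate_structure("GCGCGCGCGC", rbind(c(1, 6), c(3, 9)),
                       pairing_rule("homopolymer", 1L)),
    class = "rnanetdeg_pseudoknot")
})

test_that("dot-bracket round trips, including the Y RNA worked example", {
  expect_equal(parse_dot_bracket("((...))"), rbind(c(1L, 7L), c(2L, 6L)))
  expect_equal(nrow(parse_dot_bracket(".....")), 0L)
  expect_equal(write_dot_bracket(rbind(c(1, 7), c(2, 6)), n = 7), "((...))")
  expect_equal(write_dot_bracket(NULL, n = 4), "....")
  expect_error(parse_dot_bracket("(()"), class = "rnanetdeg_unbalanced_brackets")
  expect_error(parse_dot_bracket("())"), class = "rnanetdeg_unbalanced_brackets")

  y <- yrna_example()
  pm <- parse_dot_bracket(y$dot_bracket)
  expect_equal(nrow(pm), 23L)
  # the experimentally derived reference structure contains the
  # non-canonical pair C15.U85, so the Watson-Crick validator rejects it ...
  expect_error(validate_structure(y$sequence, pm),
               class = "rnanetdeg_not_a_pair")
  # ... but it is well-formed (no triples/pseudoknots) under an
  # unconstrained pairing predicate
  st <- validate_structure(y$sequence, pm, pairing_rule("homopolymer", 3L))
  # exactly one external base pair, (1, 98), and visible positions 99..102
  ld <- rnanetdeg:::loop_decomposition(st$pairs, st$n)
  ext <- st$pairs[ld$parent == 0L, , drop = FALSE]
  expect_equal(unname(ext), matrix(c(1L, 98L), 1L))
  paired <- logical(st$n); paired[c(st$pairs)] <- TRUE
  expect_equal(which(ld$enc == 0L & !paired), 99:102)
  expect_equal(write_dot_bracket(st), y$dot_bracket)
})

test_that("enumeration yields the known ensemble sizes deterministically", {
  expect_length(enumerate_structures("GGGGCCC"), 8L)
  expect_length(enumerate_structures("ACGUACGUACGU"), 35L)
  expect_length(enumerate_structures("AAAA"), 1L)
  expect_error(enumerate_structures(strrep("GC", 30)),
               class = "rnanetdeg_sequence_too_long")
  a <- vapply(enumerate_structures("GGGGCCC"), write_dot_bracket, "")
  b <- vapply(enumerate_structures("GGGGCCC"), write_dot_bracket, "")
  expect_identical(a, b)
})

test_that("neighbor generation matches hand-checked cases", {
  empty <- validate_structure("GGGGCCC", NULL)
  expect_length(neighbors("GGGGCCC", empty, "MS2"), 6L)  # one per addable pair
  expect_length(neighbors("GGGGCCC", empty, "SHIFT_ONLY"), 0L)
  two <- validate_structure("GGGGCCC", rbind(c(1, 7), c(2, 6)))
  expect_length(neighbors("GGGGCCC", two, "MS2"), 2L)    # remove either pair
})

test_that("moves are reversible and MS2 = MS1 plus shift-only, disjointly", {
  set.seed(101)
  rule <- pairing_rule()
  for (rep in 1:4) {
    s <- rand_rna(sample(6:10, 1))
    nodes <- enumerate_structures(s, rule)
    keys <- vapply(nodes, function(x) write_dot_bracket(x), "")
    for (ms in c("MS1", "MS2", "SHIFT_ONLY")) {
      nb <- lapply(nodes, function(x)
        vapply(neighbors(s, x, ms, rule),
               function(e) write_dot_bracket(e$structure), ""))
      for (a in seq_along(nodes)) {
        for (tkey in nb[[a]]) {
          b <- match(tkey, keys)
          expect_true(keys[a] %in% nb[[b]])       # reversibility
        }
      }
    }
    for (x in nodes) {
      n1 <- count_neighbors(s, x, "MS1", rule)
      n2 <- count_neighbors(s, x, "MS2", rule)
      nsft <- count_neighbors(s, x, "SHIFT_ONLY", rule)
      expect_identical(n1 + nsft, n2)
    }
  }
})

test_that("MS1 adjacency coincides with base-pair distance one", {
  rule <- pairing_rule()
  for (s in c("ACGUACGUACGU", "GGGGCCC")) {
    nodes <- enumerate_structures(s, rule)
    keys <- vapply(nodes, write_dot_bracket, "")
    pairsets <- lapply(nodes, function(x)
      paste(x$pairs[, 1], x$pairs[, 2], sep = "."))
    for (a in seq_along(nodes)) {
      nb <- vapply(neighbors(s, nodes[[a]], "MS1", rule),
                   function(e) write_dot_bracket(e$structure), "")
      for (b in seq_along(nodes)) {
        dbp <- length(setdiff(pairsets[[a]], pairsets[[b]])) +
          length(setdiff(pairsets[[b]], pairsets[[a]]))
        expect_identical(keys[b] %in% nb, dbp == 1L)
      }
    }
  }
})

test_that("networks reproduce the worked examples and connectivity facts", {
  net <- build_network("GGGGCCC", "MS2")
  expect_length(net$nodes, 8L)
  expect_equal(nrow(net$edges), 16L)
  expect_equal(net$directed_edge_count, 32L)
  expect_equal(net$directed_edge_count, 2L * nrow(net$edges))

  ms1 <- build_network("ACGUACGUACGU", "MS1")
  expect_equal(ms1$directed_edge_count, 126L)
  expect_true(network_is_connected(ms1))
  sft <- build_network("ACGUACGUACGU", "SHIFT_ONLY")
  expect_equal(sft$directed_edge_count, 68L)
  expect_false(network_is_connected(sft))
  expect_true(network_is_connected(build_network("ACGUACGUACGU", "MS2")))

  ed <- tempfile(fileext = ".tsv"); nd <- tempfile(fileext = ".tsv")
  write_network_tsv(net, ed, nd)
  edges <- read.delim(ed)
  expect_equal(nrow(edges), 16L)
  expect_true(all(edges$move_class %in% c("addremove", "shift")))
  expect_equal(nrow(read.delim(nd)), 8L)
})

test_that("brute-force expected degree reproduces the toy values", {
  b2 <- brute_force_expected_degree("GGGGCCC", "MS2")
  expect_identical(b2$degree, 4)
  b1 <- brute_force_expected_degree("GGGGCCC", "MS1")
  expect_identical(b1$Q, 16)
  expect_identical(b1$degree, 2)
  bb <- brute_force_expected_degree("ACGUACGUACGU", "MS2")
  expect_equal(bb$degree, 194 / 35)
})
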