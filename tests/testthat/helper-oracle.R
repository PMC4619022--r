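# Shared helpers: random sequences and enumeration-based oracles.

rand_rna <- function(len, gc = 0.5) {
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE, prob = prob),
        collapse = "")
}

oracle_Q <- function(seq, ms, rule = pairing_rule(), restricted = FALSE,
                     params = NULL) {
  nodes <- enumerate_structures(seq, rule, force = TRUE)
  degs <- vapply(nodes, function(s)
    count_neighbors(seq, s, ms, rule, restricted), 0L)
  if (is.null(params)) {
    list(Q = sum(degs), Z = length(nodes))
  } else {
    w <- vapply(nodes, function(s)
      exp(-energy_of_structure(seq, s, params)$total / params$rt), 0)
    list(Q = sum(w * degs), Z = sum(w))
  }
}

# enumeration statistics for the homopolymer model at a given theta
homopolymer_oracle <- function(n, theta = 1L) {
  rule <- pairing_rule("homopolymer", theta)
  seq <- strrep("A", max(n, 1L))
  nodes <- if (n == 0L) list() else enumerate_structures(seq, rule, force = TRUE)
  if (n == 0L) {
    return(list(Z = 1, E = 0, Q_ms1 = 0, Q_ms2 = 0, f = c(`0` = 1)))
  }
  ext <- vapply(nodes, function(s) {
    if (!nrow(s$pairs)) return(0L)
    sum(rnanetdeg:::loop_decomposition(s$pairs, n)$parent == 0L)
  }, 0L)
  vis <- vapply(nodes, function(s) {
    paired <- logical(n)
    if (nrow(s$pairs)) paired[c(s$pairs)] <- TRUE
    ld <- rnanetdeg:::loop_decomposition(s$pairs, n)
    sum(ld$enc == 0L & !paired)
  }, 0L)
  list(Z = length(nodes),
       E = sum(ext),
       Q_ms1 = sum(vapply(nodes, function(s)
         count_neighbors(seq, s, "MS1", rule), 0L)),
       Q_ms2 = sum(vapply(nodes, function(s)
         count_neighbors(seq, s, "MS2", rule), 0L)),
       f = table(vis))
}

# direct (set-enumeration) arc counts used to validate the prefix-sum
# accessors
direct_arc1a <- function(seq, i, j, rule = pairing_rule()) {
  seq <- parse_sequence(seq)
  cnt <- 0L
  if (j > i) for (x in i:(j - 1L)) for (y in (x + 1L):j) {
    if (y - x > rule$theta &&
        can_pair(seq, x, y, rule)) cnt <- cnt + 1L
  }
  cnt
}
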