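# FASTA input/output, JSON degree reports and the seeded fixture generator.

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of normalized RNA sequences.
#' @export
read_fasta_sequences <- function(path) {
  xs <- Biostrings::readBStringSet(path)
  out <- vapply(as.character(xs), function(s) parse_sequence(s)$string, "")
  names(out) <- sub("[[:space:]].*$", "", names(xs))
  out
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @export
write_fasta_sequences <- function(sequences, path) {
  xs <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(xs, path)
  invisible(path)
}

# The 102-nt Y RNA worked example (EMBL AAPY01489510:220-119) and its
# reference secondary structure in dot-bracket notation.
YRNA_SEQUENCE <- paste0(
  "GGCUGGUCCGAGUGCAGUGGUGUUUACAACUAAUUGAUCACAGCCAGUUACAGAUUCCUUUGUU",
  "CCUUCUCUACUCCCACUGCUUCACUUGACUAGCCUUUU")
YRNA_STRUCTURE <- paste0(
  "((((((((.((..(((((((.(.....(((.((.........................)).)))",
  "...........))))))...))..))))))))))....")

#' Worked-example Y RNA sequence and structure
#'
#' The 102-nt Y RNA (EMBL accession AAPY01489510:220-119) with its reference
#' secondary structure; its single external base pair is (1, 98) and
#' positions 99-102 are the only visible positions.
#'
#' @return List with `sequence` and `dot_bracket`.
#' @export
yrna_example <- function() {
  list(sequence = YRNA_SEQUENCE, dot_bracket = YRNA_STRUCTURE)
}

#' Generate a reproducible fixture set of RNA sequences
#'
#' The three canonical worked-example sequences (GGGGCCC, ACGUACGUACGU and
#' the 102-nt Y RNA) plus `count` random sequences drawn with the given GC
#' bias; byte-identical for a given seed.
#'
#' @param seed Integer RNG seed.
#' @param count Number of random sequences (>= 0).
#' @param min_len,max_len Length range of the random sequences.
#' @param gc_bias Probability mass on G/C (0.5 = uniform over the alphabet).
#' @param path Optional FASTA output path.
#' @return Object of class `fixture_set`: list with `seed` and `sequences`
#'   (named character vector).
#' @export
generate_fixtures <- function(seed = 1L, count = 10L, min_len = 8L,
                              max_len = 16L, gc_bias = 0.5, path = NULL) {
  if (min_len > max_len || count < 0L || gc_bias < 0 || gc_bias > 1) {
    cond_stop("rnanetdeg_bad_range", "invalid fixture parameters")
  }
  seqs <- c(toy_hairpin = "GGGGCCC",
            toy_12mer = "ACGUACGUACGU",
            yrna_102 = YRNA_SEQUENCE)
  if (count > 0L) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    prob <- c(A = (1 - gc_bias) / 2, C = gc_bias / 2,
              G = gc_bias / 2, U = (1 - gc_bias) / 2)
    rnd <- vapply(seq_len(count), function(k) {
      len <- sample(min_len:max_len, 1L)
      paste(sample(names(prob), len, replace = TRUE, prob = prob),
            collapse = "")
    }, "")
    names(rnd) <- sprintf("random_%03d", seq_len(count))
    seqs <- c(seqs, rnd)
  }
  fx <- structure(list(seed = as.integer(seed), sequences = seqs),
                  class = "fixture_set")
  if (!is.null(path)) write_fasta_sequences(seqs, path)
  fx
}

#' @export
print.fixture_set <- function(x, ...) {
  cat(sprintf("fixture set (seed %d): %d sequences\n",
              x$seed, length(x$sequences)))
  invisible(x)
}

#' Assemble a degree report
#'
#' Canonical serializable record of an expected-degree computation.
#'
#' @param sequence_id,sequence Identifiers.
#' @param model `"A"`, `"B"` or `"C"`.
#' @param moveset Move set id.
#' @param theta Steric parameter.
#' @param parameter_set_id Energy parameter label (model C).
#' @param Q,Z Totals; `expected_degree = Q/Z` and
#'   `normalized_degree = Q/(n Z)` are derived.
#' @param undirected_edges,directed_edge_count Optional oracle edge counts.
#' @return List of class `degree_report`.
#' @export
degree_report <- function(sequence_id, sequence, model, moveset, theta,
                          Q, Z, parameter_set_id = NULL,
                          undirected_edges = NULL,
                          directed_edge_count = NULL) {
  n <- nchar(sequence)
  rep <- list(sequence_id = sequence_id, sequence = sequence, model = model,
              moveset = moveset, theta = theta,
              parameter_set_id = parameter_set_id,
              Z = Z, Q = Q, expected_degree = Q / Z,
              normalized_degree = Q / Z / n,
              undirected_edges = undirected_edges,
              directed_edge_count = directed_edge_count)
  rep <- rep[!vapply(rep, is.null, TRUE)]
  class(rep) <- "degree_report"
  rep
}

#' @export
print.degree_report <- function(x, ...) {
  cat(format_report_json(x), "\n")
  invisible(x)
}

#' Serialize / parse degree reports as JSON
#'
#' @param report A `degree_report` (or any list).
#' @return `format_report_json`: JSON string (12 significant digits);
#'   `parse_report_json`: the parsed report.
#' @export
format_report_json <- function(report) {
  jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                   pretty = TRUE)
}

#' @rdname format_report_json
#' @param text JSON text.
#' @export
parse_report_json <- function(text) {
  rep <- jsonlite::fromJSON(text)
  class(rep) <- "degree_report"
  rep
}
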