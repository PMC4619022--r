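# Sequence and pairing-rule types.

#' Parse an RNA sequence
#'
#' Normalizes a nucleotide string to the RNA alphabet `A, C, G, U`:
#' lower-case letters are raised, `T` is mapped to `U`, whitespace is
#' stripped, and FASTA header lines (starting with `>`) are skipped.
#'
#' @param text A character scalar (or vector of lines) holding the sequence,
#'   optionally in FASTA format.
#' @return An object of class `rna_seq`: a list with elements `string`
#'   (normalized sequence), `codes` (integer codes, A=1, C=2, G=3, U=4) and
#'   `n` (sequence length).
#' @examples
#' parse_sequence("GGGGCCC")
#' parse_sequence("acgt")$string  # "ACGU"
#' @export
parse_sequence <- function(text) {
  if (inherits(text, "rna_seq")) return(text)
  stopifnot(is.character(text))
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- lines[!startsWith(trimws(lines), ">")]
  s <- gsub("[[:space:]]", "", paste(lines, collapse = ""))
  if (nchar(s) == 0L) {
    cond_stop("rnanetdeg_empty_input", "empty sequence input")
  }
  s <- chartr("acgut", "ACGUU", s)
  s <- chartr("T", "U", s)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  codes <- match(chars, RNA_ALPHABET)
  if (anyNA(codes)) {
    pos <- which(is.na(codes))[1L]
    cond_stop("rnanetdeg_illegal_symbol",
              sprintf("illegal symbol '%s' at position %d", chars[pos], pos),
              position = pos)
  }
  structure(list(string = s, codes = codes, n = length(codes)),
            class = "rna_seq")
}

#' @export
print.rna_seq <- function(x, ...) {
  cat(sprintf("RNA sequence (%d nt): %s\n", x$n, x$string))
  invisible(x)
}

#' Pairing rule
#'
#' A pairing rule bundles the minimum number `theta` of unpaired bases that
#' must separate the two positions of a base pair with the predicate deciding
#' which nucleotide pairs may form.  Mode `"wc_wobble"` admits Watson-Crick
#' (AU, UA, CG, GC) and wobble (GU, UG) pairs with a default `theta = 3`;
#' mode `"homopolymer"` admits every nucleotide combination with a default
#' `theta = 1`, which is the convention of the homopolymer counting model.
#'
#' @param mode `"wc_wobble"` or `"homopolymer"`.
#' @param theta Non-negative integer; defaults to 3 (`wc_wobble`) or
#'   1 (`homopolymer`).
#' @return Object of class `pairing_rule`.
#' @export
pairing_rule <- function(mode = c("wc_wobble", "homopolymer"), theta = NULL) {
  mode <- match.arg(mode)
  if (is.null(theta)) theta <- if (mode == "wc_wobble") 3L else 1L
  theta <- as.integer(theta)
  stopifnot(length(theta) == 1L, theta >= 0L)
  structure(list(mode = mode, theta = theta), class = "pairing_rule")
}

#' Can positions i and j form a base pair?
#'
#' True iff `j - i > theta` and the nucleotides at `i, j` are admissible under
#' the rule's pairing predicate.
#'
#' @param seq An `rna_seq` (or string coercible to one).
#' @param i,j Positions with `1 <= i < j <= n` (1-based).
#' @param rule A [pairing_rule()].
#' @return Logical scalar.
#' @export
can_pair <- function(seq, i, j, rule = pairing_rule()) {
  seq <- parse_sequence(seq)
  i <- as.integer(i); j <- as.integer(j)
  if (any(i < 1L) || any(j > seq$n) || any(i >= j)) {
    cond_stop("rnanetdeg_index_out_of_range",
              "require 1 <= i < j <= n")
  }
  sep_ok <- (j - i) > rule$theta
  if (rule$mode == "homopolymer") return(sep_ok)
  sep_ok & WC_WOBBLE[cbind(seq$codes[i], seq$codes[j])]
}

# n x n logical matrix: bp_mat[i, j] TRUE iff (i, j) with i < j may pair
# under `rule` (theta folded in, so every summation bound downstream is safe).
bp_matrix <- function(seq, rule) {
  n <- seq$n
  m <- matrix(FALSE, n, n)
  if (n < rule$theta + 2L) return(m)
  ij <- which(upper.tri(m), arr.ind = TRUE)
  ij <- ij[ij[, 2L] - ij[, 1L] > rule$theta, , drop = FALSE]
  if (nrow(ij)) {
    ok <- if (rule$mode == "homopolymer") TRUE
          else WC_WOBBLE[cbind(seq$codes[ij[, 1L]], seq$codes[ij[, 2L]])]
    m[ij[ok, , drop = FALSE]] <- TRUE
  }
  m
}

# logical vector over positions: can position k pair with nucleotide code c?
# (theta-free; used for the visible-occurrence tables F and G).
bp_with_code <- function(seq, code, rule) {
  if (rule$mode == "homopolymer") rep(TRUE, seq$n)
  else WC_WOBBLE[seq$codes, code]
}
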