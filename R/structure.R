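# Secondary-structure type: validation, dot-bracket I/O, loop decomposition.

new_structure <- function(pairs, n) {
  if (is.null(pairs) || length(pairs) == 0L) {
    pairs <- matrix(integer(0), 0L, 2L)
  }
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  if (nrow(pairs)) pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  colnames(pairs) <- c("i", "j")
  structure(list(pairs = pairs, n = as.integer(n)),
            class = "secondary_structure")
}

as_pair_matrix <- function(pairs) {
  if (inherits(pairs, "secondary_structure")) return(pairs$pairs)
  if (is.null(pairs) || length(pairs) == 0L) return(matrix(integer(0), 0L, 2L))
  if (is.list(pairs) && !is.data.frame(pairs)) {
    pairs <- do.call(rbind, lapply(pairs, function(p) as.integer(p)))
  }
  pairs <- matrix(as.integer(as.matrix(pairs)), ncol = 2L)
  swap <- pairs[, 1L] > pairs[, 2L]
  pairs[swap, ] <- pairs[swap, c(2L, 1L)]
  pairs
}

#' Validate a secondary structure
#'
#' Checks the four defining conditions of a (pseudoknot-free) secondary
#' structure against a sequence and pairing rule: every pair must be
#' admissible under the pairing predicate, satisfy the steric constraint
#' `j - i > theta`, no position may occur in more than one pair (no base
#' triples), and no two pairs may cross (no pseudoknots).
#'
#' @param seq An `rna_seq` or string.
#' @param pairs A two-column matrix / list of `(i, j)` base pairs, 1-based.
#' @param rule A [pairing_rule()].
#' @return A `secondary_structure` object (pairs sorted by `i`).
#' @examples
#' validate_structure("GGGGCCC", rbind(c(1, 7), c(2, 6)))
#' @export
validate_structure <- function(seq, pairs, rule = pairing_rule()) {
  seq <- parse_sequence(seq)
  pm <- as_pair_matrix(pairs)
  n <- seq$n
  if (nrow(pm)) {
    if (any(pm < 1L) || any(pm > n)) {
      cond_stop("rnanetdeg_index_out_of_range", "pair position outside [1, n]")
    }
    sep <- pm[, 2L] - pm[, 1L]
    if (any(sep <= rule$theta)) {
      k <- which(sep <= rule$theta)[1L]
      cond_stop("rnanetdeg_steric_violation",
                sprintf("pair (%d,%d) violates j - i > theta = %d",
                        pm[k, 1L], pm[k, 2L], rule$theta))
    }
    if (rule$mode != "homopolymer") {
      ok <- WC_WOBBLE[cbind(seq$codes[pm[, 1L]], seq$codes[pm[, 2L]])]
      if (!all(ok)) {
        k <- which(!ok)[1L]
        cond_stop("rnanetdeg_not_a_pair",
                  sprintf("nucleotides at (%d,%d) cannot pair",
                          pm[k, 1L], pm[k, 2L]))
      }
    }
    occ <- c(pm[, 1L], pm[, 2L])
    if (anyDuplicated(occ)) {
      cond_stop("rnanetdeg_base_triple",
                sprintf("position %d occurs in more than one pair",
                        occ[duplicated(occ)][1L]))
    }
    if (nrow(pm) > 1L) {
      o <- order(pm[, 1L])
      pi1 <- pm[o, 1L]; pj1 <- pm[o, 2L]
      for (a in seq_len(nrow(pm) - 1L)) {
        b <- which(pi1 > pi1[a] & pi1 < pj1[a] & pj1 > pj1[a])
        if (length(b)) {
          cond_stop("rnanetdeg_pseudoknot",
                    sprintf("pairs (%d,%d) and (%d,%d) cross",
                            pi1[a], pj1[a], pi1[b[1L]], pj1[b[1L]]))
        }
      }
    }
  }
  new_structure(pm, n)
}

#' Parse dot-bracket notation
#'
#' @param text A string over `.`, `(` and `)`.
#' @return Two-column integer matrix of 1-based base pairs (possibly empty).
#' @examples
#' parse_dot_bracket("((...))")
#' @export
parse_dot_bracket <- function(text) {
  chars <- strsplit(gsub("[[:space:]]", "", text), "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c(".", "(", ")"))
  if (length(bad)) {
    cond_stop("rnanetdeg_illegal_symbol",
              sprintf("illegal dot-bracket symbol '%s' at position %d",
                      chars[bad[1L]], bad[1L]))
  }
  open <- integer(0)
  out <- vector("list", sum(chars == ")"))
  k <- 0L
  for (pos in seq_along(chars)) {
    if (chars[pos] == "(") {
      open <- c(open, pos)
    } else if (chars[pos] == ")") {
      if (!length(open)) {
        cond_stop("rnanetdeg_unbalanced_brackets",
                  sprintf("unmatched ')' at position %d", pos))
      }
      k <- k + 1L
      out[[k]] <- c(open[length(open)], pos)
      open <- open[-length(open)]
    }
  }
  if (length(open)) {
    cond_stop("rnanetdeg_unbalanced_brackets",
              sprintf("unmatched '(' at position %d", open[1L]))
  }
  pm <- as_pair_matrix(out)
  pm[order(pm[, 1L]), , drop = FALSE]
}

#' Write dot-bracket notation
#'
#' Inverse of [parse_dot_bracket()] for pseudoknot-free structures.
#'
#' @param s A `secondary_structure`, or a pair matrix (then `n` is required).
#' @param n Sequence length when `s` is a bare pair set.
#' @return A dot-bracket string of length `n`.
#' @export
write_dot_bracket <- function(s, n = NULL) {
  if (inherits(s, "secondary_structure")) {
    pm <- s$pairs; n <- s$n
  } else {
    pm <- as_pair_matrix(s)
    stopifnot(!is.null(n))
  }
  chars <- rep(".", n)
  chars[pm[, 1L]] <- "("
  chars[pm[, 2L]] <- ")"
  paste(chars, collapse = "")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("secondary structure on %d nt, %d base pairs\n  %s\n",
              x$n, nrow(x$pairs), write_dot_bracket(x)))
  invisible(x)
}

#' @export
format.secondary_structure <- function(x, ...) write_dot_bracket(x)

# canonical key for hashing/sorting structures (lexicographic on the
# sorted pair list)
structure_key <- function(pm) {
  if (!is.matrix(pm)) pm <- pm$pairs
  if (!nrow(pm)) return("empty")
  pm <- pm[order(pm[, 1L]), , drop = FALSE]
  paste(sprintf("%04d.%04d", pm[, 1L], pm[, 2L]), collapse = ";")
}

# Loop decomposition.  For a valid structure, returns
#   enc:    for every position, id of the innermost pair (i,j) with
#           i <= k <= j (0 = exterior); endpoints map to their own pair
#   parent: for every pair id, the id of the enclosing pair (0 = exterior)
#   children: list over loops (index 1 = exterior, index p+1 = pair p) of
#           child pair ids, ordered left to right
# Pair ids refer to rows of the i-sorted pair matrix.
loop_decomposition <- function(pm, n) {
  if (!is.matrix(pm)) { n <- pm$n; pm <- pm$pairs }
  np <- nrow(pm)
  enc <- integer(n)
  parent <- integer(np)
  left_at <- integer(n); right_at <- integer(n)
  if (np) {
    left_at[pm[, 1L]] <- seq_len(np)
    right_at[pm[, 2L]] <- seq_len(np)
  }
  stack <- integer(0)
  top <- 0L
  for (k in seq_len(n)) {
    p <- left_at[k]
    if (p) {
      parent[p] <- top
      stack <- c(stack, p)
      top <- p
      enc[k] <- p
    } else {
      q <- right_at[k]
      if (q) {
        enc[k] <- q
        stack <- stack[-length(stack)]
        top <- if (length(stack)) stack[length(stack)] else 0L
      } else {
        enc[k] <- top
      }
    }
  }
  children <- vector("list", np + 1L)
  for (l in 0:np) children[[l + 1L]] <- integer(0)
  if (np) {
    for (p in seq_len(np)) {
      children[[parent[p] + 1L]] <- c(children[[parent[p] + 1L]], p)
    }
    # order children left to right
    children <- lapply(children, function(cs) cs[order(pm[cs, 1L])])
  }
  list(enc = enc, parent = parent, children = children)
}
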