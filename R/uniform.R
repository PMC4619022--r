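# Uniform (zero-energy) counting model for real sequences: every structure
# of Definition-style validity (Watson-Crick/wobble pairs, j - i > theta = 3)
# has weight 1, so Z_{i,j} counts structures of a[i..j] and Q_{1,n} counts
# directed move-set edges.  The auxiliary tables EL/ER/ERp (external-pair
# reservoirs feeding shift moves that re-anchor onto a boundary position) and
# F/G (refinements by the number of visible positions pairable with a given
# nucleotide) are indexed by interval and nucleotide class.
#
# All arithmetic is integer-valued double precision (exact below 2^53, far
# above any enumerable scale); the steric constraint is folded into the pair
# predicate so every summation bound is safe.

#' Uniform-model dynamic-programming tables
#'
#' Fills the interval tables of the uniform counting model: structure counts
#' `Z[i,j]`, the external-pair reservoirs `EL`, `ER`, `ERp` (indexed by a
#' nucleotide class `c`), the visible-position refinements `F[i,j,c,x]` and
#' `G[i,j,c,x]`, and the directed move totals `Q[i,j]` for MS1, MS2 and
#' shift-only.
#'
#' @param seq An `rna_seq` or string.
#' @param rule A [pairing_rule()]; `"homopolymer"` mode reproduces the
#'   homopolymer model on intervals (useful for cross-checking).
#' @return Object of class `uniform_tables` with components `Z`, `EL`, `ER`,
#'   `ERp`, `F`, `G`, `Q_ms1`, `Q_ms2`, `Q_shift` (matrices/arrays indexed so
#'   that column `j + 1` holds interval end `j`, with `j = i - 1` the empty
#'   interval).
#' @examples
#' tb <- compute_uniform_tables("GGGGCCC")
#' uniform_Z(tb, 1, 7)  # 8 structures
#' @export
compute_uniform_tables <- function(seq, rule = pairing_rule()) {
  seq <- parse_sequence(seq)
  n <- seq$n
  theta <- rule$theta
  B <- bp_matrix(seq, rule)
  bpc <- vapply(1:4, function(cc) bp_with_code(seq, cc, rule),
                logical(n))                       # n x 4: position vs class
  # column index j+1 so the empty interval j = i-1 is addressable
  jx <- function(j) j + 1L
  Z <- matrix(1, n + 1L, n + 1L)                  # Z[i, jx(j)]
  EL <- array(0, c(n + 1L, n + 1L, 4L))
  ER <- array(0, c(n + 1L, n + 1L, 4L))
  ERp <- array(0, c(n + 1L, n + 1L, 4L))
  FF <- array(0, c(n + 1L, n + 1L, 4L, n + 2L))   # x slot = x + 1
  GG <- array(0, c(n + 1L, n + 1L, 4L, n + 2L))
  Q1 <- matrix(0, n + 1L, n + 1L)
  Q2 <- matrix(0, n + 1L, n + 1L)
  QS <- matrix(0, n + 1L, n + 1L)

  # F base cases: empty interval (x = 0) and single positions
  for (i in 1:(n + 1L)) FF[i, jx(i - 1L), , 1L] <- 1
  for (i in 1:n) for (cc in 1:4) {
    FF[i, jx(i), cc, 1L + bpc[i, cc]] <- 1
  }

  for (d in 1:(n - 1L)) {
    for (i in 1:(n - d)) {
      j <- i + d
      aj <- seq$codes[j]
      if (d <= theta) {
        for (cc in 1:4) {
          if (bpc[j, cc]) {
            FF[i, jx(j), cc, 2:(n + 2L)] <- FF[i, jx(j - 1L), cc, 1:(n + 1L)]
          } else {
            FF[i, jx(j), cc, ] <- FF[i, jx(j - 1L), cc, ]
          }
        }
        next
      }
      ks <- i:(j - theta - 1L)
      ks <- ks[B[ks, j]]
      # Z
      zacc <- Z[i, jx(j - 1L)]
      for (k in ks) zacc <- zacc + Z[i, jx(k - 1L)] * Z[k + 1L, jx(j - 1L)]
      Z[i, jx(j)] <- zacc
      # EL / ER
      for (cc in 1:4) {
        el <- EL[i, jx(j - 1L), cc]
        er <- ER[i, jx(j - 1L), cc]
        for (k in ks) {
          zin <- Z[k + 1L, jx(j - 1L)]
          if (k == i) {
            el <- el + bpc[i, cc] * zin
            er <- er + bpc[j, cc] * zin
          } else {
            el <- el + (EL[i, jx(k - 1L), cc] + bpc[k, cc] * Z[i, jx(k - 1L)]) * zin
            er <- er + (ER[i, jx(k - 1L), cc] + bpc[j, cc] * Z[i, jx(k - 1L)]) * zin
          }
        }
        EL[i, jx(j), cc] <- el
        ER[i, jx(j), cc] <- er
      }
      # ERp: external pairs (x, y) with y <= j - theta - 1, j unpaired;
      # decomposition over the rightmost paired position m in the tail
      for (cc in 1:4) {
        v <- ER[i, jx(j - theta - 1L), cc]
        for (u in 1:theta) {
          m <- j - theta - 1L + u
          if (m - theta - 1L >= i + 1L) {
            for (k in (i + 1L):(m - theta - 1L)) {
              if (B[k, m]) {
                v <- v + ER[i, jx(k - 1L), cc] * Z[k + 1L, jx(m - 1L)]
              }
            }
          }
        }
        ERp[i, jx(j), cc] <- v
      }
      # F
      for (cc in 1:4) {
        if (bpc[j, cc]) {
          v <- c(0, FF[i, jx(j - 1L), cc, 1:(n + 1L)])
        } else {
          v <- FF[i, jx(j - 1L), cc, ]
        }
        for (k in ks) {
          zin <- Z[k + 1L, jx(j - 1L)]
          if (k == i) {
            v[1L] <- v[1L] + zin            # pair (i, j): nothing visible
          } else {
            v <- v + FF[i, jx(k - 1L), cc, ] * zin
          }
        }
        FF[i, jx(j), cc, ] <- v
      }
      # G: j unpaired, x visible pairable positions within [i, j - theta - 1]
      for (cc in 1:4) {
        v <- FF[i, jx(j - theta - 1L), cc, ]
        for (u in 1:theta) {
          m <- j - theta - 1L + u
          if (m - theta - 1L < i) next
          for (k in i:(m - theta - 1L)) {
            if (!B[k, m]) next
            zin <- Z[k + 1L, jx(m - 1L)]
            if (k == i) {
              v[1L] <- v[1L] + zin
            } else {
              v <- v + FF[i, jx(k - 1L), cc, ] * zin
            }
          }
        }
        GG[i, jx(j), cc, ] <- v
      }
      # Q for the three move sets
      addrem <- 0
      inner1 <- 0; inner2 <- 0; inners <- 0
      for (k in ks) {
        zl <- Z[i, jx(k - 1L)]; zin <- Z[k + 1L, jx(j - 1L)]
        addrem <- addrem + zl * zin
        inner1 <- inner1 + Q1[i, jx(k - 1L)] * zin + zl * Q1[k + 1L, jx(j - 1L)]
        inner2 <- inner2 + Q2[i, jx(k - 1L)] * zin + zl * Q2[k + 1L, jx(j - 1L)]
        inners <- inners + QS[i, jx(k - 1L)] * zin + zl * QS[k + 1L, jx(j - 1L)]
      }
      xs <- 0:(n + 1L)
      shift_g <- sum(xs * (xs - 1) * GG[i, jx(j), aj, ])
      shift_e <- 2 * (EL[i, jx(j - 1L), aj] + ERp[i, jx(j), aj])
      Q1[i, jx(j)] <- Q1[i, jx(j - 1L)] + 2 * addrem + inner1
      Q2[i, jx(j)] <- Q2[i, jx(j - 1L)] + 2 * addrem + shift_e + shift_g + inner2
      QS[i, jx(j)] <- QS[i, jx(j - 1L)] + shift_e + shift_g + inners
    }
  }

  structure(list(sequence = seq$string, theta = theta, rule = rule,
                 n = n, Z = Z, EL = EL, ER = ER, ERp = ERp, F = FF, G = GG,
                 Q_ms1 = Q1, Q_ms2 = Q2, Q_shift = QS),
            class = "uniform_tables")
}

#' @export
print.uniform_tables <- function(x, ...) {
  cat(sprintf("uniform-model tables for %s (theta = %d): Z = %g, Q(MS1) = %g, Q(MS2) = %g\n",
              x$sequence, x$theta, uniform_Z(x), x$Q_ms1[1L, x$n + 1L],
              x$Q_ms2[1L, x$n + 1L]))
  invisible(x)
}

#' Interval structure count from uniform tables
#' @param tables A `uniform_tables` object.
#' @param i,j Interval bounds (defaults: whole sequence).
#' @export
uniform_Z <- function(tables, i = 1L, j = tables$n) tables$Z[i, j + 1L]

#' Total directed move count Q of the uniform model
#'
#' `Q_{1,n}` equals the sum over all structures of the neighbor count under
#' the chosen move set; `Q(MS1) + Q(SHIFT_ONLY) = Q(MS2)` by construction.
#'
#' @param seq Sequence, or a precomputed [compute_uniform_tables()] object.
#' @param ms Move set.
#' @param rule A [pairing_rule()].
#' @return Numeric scalar (exact integer value).
#' @examples
#' uniform_Q("GGGGCCC", "MS2")        # 32
#' uniform_Q("ACGUACGUACGU", "MS1")   # 126
#' @export
uniform_Q <- function(seq, ms = c("MS2", "MS1", "SHIFT_ONLY"),
                      rule = pairing_rule()) {
  ms <- match.arg(ms)
  tb <- if (inherits(seq, "uniform_tables")) seq
        else compute_uniform_tables(seq, rule)
  q <- switch(ms, MS1 = tb$Q_ms1, MS2 = tb$Q_ms2, SHIFT_ONLY = tb$Q_shift)
  q[1L, tb$n + 1L]
}

#' Uniform expected network degree
#'
#' @inheritParams uniform_Q
#' @return List with `Q`, `Z`, `degree = Q/Z` and
#'   `normalized_degree = Q/(n Z)`.
#' @examples
#' uniform_expected_degree("ACGUACGUACGU", "MS2")$degree  # 194/35
#' @export
uniform_expected_degree <- function(seq, ms = c("MS2", "MS1", "SHIFT_ONLY"),
                                    rule = pairing_rule()) {
  ms <- match.arg(ms)
  tb <- if (inherits(seq, "uniform_tables")) seq
        else compute_uniform_tables(seq, rule)
  Q <- uniform_Q(tb, ms)
  Z <- uniform_Z(tb)
  list(Q = Q, Z = Z, degree = Q / Z, normalized_degree = Q / Z / tb$n)
}
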