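# Homopolymer counting model: every two positions may pair subject only to
# the steric constraint j - i > theta (default theta = 1).  Z_n counts
# structures, E_n external base pairs, f(n, x) structures with x visible
# positions, g(n, x) structures with position n unpaired and x visible
# positions in [1, n - theta - 1], and Q_n the total move count over the
# ensemble for a move set.  All quantities depend only on length, so tables
# are one-dimensional in n (plus x for f, g).
#
# Numerics: "exact" stores plain counts (doubles are exact integers below
# 2^53, guarded); "scaled" stores v_n / s^n for a growth constant s fitted
# from a first log-space pass, so ratios like Q_n/(n Z_n) stay accurate to
# >= 10 significant digits out to n ~ 2000.  See RECURSION_NOTES.md for the
# base-case audit (E_0 = 0, Q_0 = 0).

#' Homopolymer structure-count and move-count tables
#'
#' Fills the dynamic-programming tables of the homopolymer model up to
#' `n_max`: structure counts `Z`, external-pair totals `E`, the
#' visible-position refinements `f(n, x)` and `g(n, x)`, and the total move
#' counts `Q_n` for move sets MS1 (base-pair addition/removal), MS2
#' (additions/removals/shifts) and shift-only.
#'
#' @param n_max Largest length to tabulate (>= 0).
#' @param theta Minimum unpaired separation (default 1, the homopolymer
#'   convention).
#' @param representation `"exact"` (plain integer-valued doubles, guarded at
#'   2^53), `"scaled"` (values divided by s^n), or `"auto"` (exact up to
#'   n_max = 60, scaled beyond).
#' @return Object of class `homopolymer_tables`.
#' @examples
#' tb <- homopolymer_tables(10)
#' tb$Z[5 + 1]  # Z_5 = 8
#' @export
homopolymer_tables <- function(n_max, theta = 1L,
                               representation = c("auto", "exact", "scaled")) {
  representation <- match.arg(representation)
  n_max <- as.integer(n_max)
  theta <- as.integer(theta)
  if (n_max < 0L) cond_stop("rnanetdeg_negative_length", "n_max must be >= 0")
  if (representation == "auto") {
    representation <- if (n_max <= 36L) "exact" else "scaled"
  }

  s <- 1
  if (representation == "scaled" && n_max >= 20L) {
    s <- exp(homopolymer_log_growth(n_max, theta))
  }
  si <- 1 / s
  N1 <- n_max + 1L          # index shift: entry k holds value at n = k - 1
  at <- function(n) n + 1L

  # Z_n = Z_{n-1} + sum_{r=0}^{n-theta-2} Z_r Z_{n-r-2} (scaled by s^-n)
  zs <- numeric(N1)
  for (n in 0:min(theta + 1L, n_max)) zs[at(n)] <- si^n
  if (n_max > theta + 1L) {
    for (n in (theta + 2L):n_max) {
      r <- 0:(n - theta - 2L)
      zs[at(n)] <- zs[at(n - 1L)] * si +
        si^2 * sum(zs[at(r)] * zs[at(n - r - 2L)])
    }
  }

  # f(n, x): blocked prefix convolution; fs[at(n), at(x)] = f(n, x) s^-n
  fs <- matrix(0, N1, N1)
  fs[1L, 1L] <- 1
  if (n_max >= 1L) {
    block <- 64L
    n <- 1L
    Sold <- matrix(0, N1, 0L)   # placeholder
    while (n <= n_max) {
      hi <- min(n + block - 1L, n_max)
      ns <- n:hi
      # contributions from rows r <= n - theta - 2 (available before block)
      r_old <- 0:max(0L, n - theta - 2L)
      have_old <- n - theta - 2L >= 0L
      if (have_old) {
        W <- matrix(0, length(r_old), length(ns))
        for (t in seq_along(ns)) {
          rmax <- ns[t] - theta - 2L
          if (rmax >= 0L) {
            rr <- 0:min(rmax, max(r_old))
            W[seq_along(rr), t] <- zs[at(ns[t] - rr - 2L)]
          }
        }
        Sold <- crossprod(fs[at(r_old), , drop = FALSE], W)  # N1 x |ns|
      }
      for (t in seq_along(ns)) {
        m <- ns[t]
        v <- numeric(N1)
        v[2:N1] <- fs[at(m - 1L), 1:(N1 - 1L)] * si   # f(m-1, x-1)
        if (have_old) v <- v + si^2 * Sold[, t]
        # rows not covered by the pre-block product: n - theta - 1 <= r <= m - theta - 2
        r_lo <- max(n - theta - 1L, 0L)
        r_hi <- m - theta - 2L
        if (have_old && r_hi >= r_lo) {
          for (r1 in r_lo:r_hi) {
            v <- v + si^2 * fs[at(r1), ] * zs[at(m - r1 - 2L)]
          }
        } else if (!have_old && r_hi >= 0L) {
          for (r1 in 0:r_hi) {
            v <- v + si^2 * fs[at(r1), ] * zs[at(m - r1 - 2L)]
          }
        }
        fs[at(m), ] <- v
      }
      n <- hi + 1L
    }
  }

  # g(n, x) = f(n-theta-1, x) s^{theta+1} term + tail-pair terms
  gs <- matrix(0, N1, N1)
  if (n_max > theta + 1L) {
    for (n in (theta + 2L):n_max) {
      v <- fs[at(n - theta - 1L), ] * si^(theta + 1L)
      for (u in 1:theta) {
        m <- n - theta - 1L + u
        kmax <- m - theta - 1L
        if (kmax >= 1L) {
          k <- 1:kmax
          w <- zs[at(m - k - 1L)]
          v <- v + si^(n - m + 2L) *
            as.numeric(crossprod(fs[at(k - 1L), , drop = FALSE], w))
        }
      }
      gs[at(n), ] <- v
    }
  }

  # E_n
  es <- numeric(N1)
  if (n_max > theta + 1L) {
    for (n in (theta + 2L):n_max) {
      k <- 1:(n - theta - 1L)
      es[at(n)] <- es[at(n - 1L)] * si +
        si^2 * sum((es[at(k - 1L)] + zs[at(k - 1L)]) * zs[at(n - k - 1L)])
    }
  }

  # ERp_n: external pairs (x, y) with y <= n - theta - 1 over structures on
  # [1, n-1] (the shift-to-(y, n) reservoir)
  erp <- numeric(N1)
  if (n_max > theta + 1L) {
    for (n in (theta + 2L):n_max) {
      v <- es[at(n - theta - 1L)] * si^(theta + 1L)
      for (u in 1:theta) {
        m <- n - theta - 1L + u
        kmax <- m - theta - 1L
        if (kmax >= 1L) {
          k <- 1:kmax
          v <- v + si^(n - m + 2L) * sum(es[at(k - 1L)] * zs[at(m - k - 1L)])
        }
      }
      erp[at(n)] <- v
    }
  }

  # shift-move reservoir Sigma_x x(x-1) g(n, x)
  xs <- 0:n_max
  wshift <- as.numeric(gs %*% (xs * (xs - 1)))

  # Q_n for MS1 and MS2
  q1 <- numeric(N1)
  q2 <- numeric(N1)
  if (n_max > theta + 1L) {
    for (n in (theta + 2L):n_max) {
      k <- 1:(n - theta - 1L)
      addrem <- 2 * si^2 * sum(zs[at(k - 1L)] * zs[at(n - k - 1L)])
      inner1 <- si^2 * sum(zs[at(k - 1L)] * q1[at(n - k - 1L)] +
                           q1[at(k - 1L)] * zs[at(n - k - 1L)])
      inner2 <- si^2 * sum(zs[at(k - 1L)] * q2[at(n - k - 1L)] +
                           q2[at(k - 1L)] * zs[at(n - k - 1L)])
      q1[at(n)] <- q1[at(n - 1L)] * si + addrem + inner1
      q2[at(n)] <- q2[at(n - 1L)] * si + addrem +
        2 * (es[at(n - 1L)] * si + erp[at(n)]) + wshift[at(n)] + inner2
    }
  }

  tb <- structure(list(theta = theta, n_max = n_max,
                       representation = representation, scale = s,
                       Z = zs, E = es, f = fs, g = gs,
                       Q_ms1 = q1, Q_ms2 = q2, Q_shift = q2 - q1),
                  class = "homopolymer_tables")
  if (representation == "exact") {
    mx <- max(zs[N1], q2[N1])
    if (is.finite(mx) && mx >= 2^53) {
      cond_stop("rnanetdeg_overflow",
                "exact representation exceeds 2^53; use representation = \"scaled\"")
    }
  }
  tb
}

# asymptotic growth rate log(Z_n)/n via a cheap log-space pass
homopolymer_log_growth <- function(n_max, theta) {
  N <- min(max(n_max, 50L), 400L)
  lz <- numeric(N + 1L)                       # log Z_n, Z_n = 1 for small n
  for (n in (theta + 2L):N) {
    r <- 0:(n - theta - 2L)
    terms <- c(lz[n], lz[r + 1L] + lz[n - r - 1L])  # Z_{n-1}, Z_r Z_{n-r-2}
    m <- max(terms)
    lz[n + 1L] <- m + log(sum(exp(terms - m)))
  }
  n0 <- max(2L, N - 150L)
  (lz[N + 1L] - lz[n0 + 1L]) / (N - n0)
}

#' @export
print.homopolymer_tables <- function(x, ...) {
  cat(sprintf("homopolymer tables: theta = %d, n_max = %d, representation = %s\n",
              x$theta, x$n_max, x$representation))
  if (x$representation == "scaled") {
    cat(sprintf("  scale s = %.12f (stored values are v_n / s^n)\n", x$scale))
  }
  invisible(x)
}

#' Total move count Q_n of the homopolymer ensemble
#'
#' @param tables A [homopolymer_tables()] object.
#' @param ms `"MS1"`, `"MS2"` or `"SHIFT_ONLY"`.
#' @return Numeric vector over n = 0..n_max.  In the scaled representation
#'   the values carry the factor s^-n (attribute `log_scale_per_n`).
#' @export
homopolymer_Q <- function(tables, ms = c("MS2", "MS1", "SHIFT_ONLY")) {
  ms <- match.arg(ms)
  q <- switch(ms, MS1 = tables$Q_ms1, MS2 = tables$Q_ms2,
              SHIFT_ONLY = tables$Q_shift)
  if (tables$representation == "scaled") {
    attr(q, "log_scale_per_n") <- log(tables$scale)
  }
  q
}

#' Expected and normalized homopolymer network degree
#'
#' `expected`: Q_n / Z_n, the mean number of neighbors of a structure drawn
#' uniformly from the length-n homopolymer ensemble.  `normalized` divides by
#' n.  The rescaling factor cancels, so both are exact in either
#' representation.
#'
#' @inheritParams homopolymer_Q
#' @param n Length (0..n_max); vectorized.
#' @return Numeric.
#' @examples
#' tb <- homopolymer_tables(10)
#' normalized_degree(tb, "MS2", 3)  # 2 / (3 * 2)
#' @export
normalized_degree <- function(tables, ms = c("MS2", "MS1", "SHIFT_ONLY"), n) {
  n <- as.integer(n)
  if (any(n < 1L) || any(n > tables$n_max)) {
    cond_stop("rnanetdeg_index_out_of_range", "n outside 1..n_max")
  }
  homopolymer_Q(tables, ms)[n + 1L] / (n * tables$Z[n + 1L])
}

#' @rdname normalized_degree
#' @export
homopolymer_expected_degree <- function(tables,
                                        ms = c("MS2", "MS1", "SHIFT_ONLY"),
                                        n) {
  n <- as.integer(n)
  if (any(n < 0L) || any(n > tables$n_max)) {
    cond_stop("rnanetdeg_index_out_of_range", "n outside 0..n_max")
  }
  homopolymer_Q(tables, ms)[n + 1L] / tables$Z[n + 1L]
}

#' Homopolymer degree table
#'
#' Convenience summary across lengths: Z (log10), Q per move set, expected
#' and normalized degrees.
#'
#' @inheritParams homopolymer_Q
#' @param n Lengths to report (default all up to n_max).
#' @return A data frame.
#' @export
homopolymer_degree_table <- function(tables, n = seq_len(tables$n_max)) {
  n <- as.integer(n)
  lz <- log(tables$Z[n + 1L]) + n * log(tables$scale)
  data.frame(
    n = n,
    log10_Z = lz / log(10),
    degree_ms1 = homopolymer_expected_degree(tables, "MS1", n),
    degree_ms2 = homopolymer_expected_degree(tables, "MS2", n),
    normalized_ms1 = homopolymer_expected_degree(tables, "MS1", n) / n,
    normalized_ms2 = homopolymer_expected_degree(tables, "MS2", n) / n
  )
}
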