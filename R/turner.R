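# Boltzmann-weighted expected network degree under the dangle-free
# nearest-neighbour model.  Z/ZB/ZM/ZM1 are the McCaskill interval partition
# functions (ZB: (i,j) paired; ZM/ZM1: inside a multiloop, >=1 / exactly one
# component); Q/QB/QM/QM1 are the corresponding neighbor-weighted sums
# Sigma BF(s) N*(s).  N*(s) excludes a small set of multiloop moves (see the
# methods vignette); the enumeration comparator count_neighbors(...,
# restricted = TRUE) implements exactly the same taxonomy.
#
# Arc counters give, in O(1) from prefix sums, the number of base pairs
# addable inside a loop region and the number of shift targets for
# loop-boundary pairs.

#' Pairable-pair arc counters
#'
#' Prefix-sum accessors over the pair predicate: `arc1a(i, j)` counts
#' pairable (x, y) with `i <= x < y <= j`; `arc1b`/`arc1c` count shift
#' targets of a closing pair (i, j) within its loop; `arc2*` count additions
#' and boundary shifts inside an interior loop; `arc4`/`arc5` count rightward
#' shift targets of a multiloop component.  All honour the steric constraint
#' through the pair predicate.
#'
#' @param seq An `rna_seq` or string.
#' @param rule A [pairing_rule()].
#' @return List of accessor functions (`arc1a`, `arc1b`, `arc1c`, `arc2a`,
#'   `arc2b`, `arc2c`, `arc2`, `arc3`, `arc4`, `arc5`).
#' @export
arc_counts <- function(seq, rule = pairing_rule()) {
  seq <- parse_sequence(seq)
  n <- seq$n
  theta <- rule$theta
  B <- bp_matrix(seq, rule)
  Bn <- B * 1L
  # rowc[i, y]: pairable partners (i, x) with x <= y;  colc[x, j]: (x', j)
  # partners with x' <= x
  rowc <- t(apply(Bn, 1L, cumsum))
  colc <- apply(Bn, 2L, cumsum)
  rcount <- function(i, a, b) {            # |{x in [a,b]: bp(i, x), x > i}|
    if (b < a || i < 1L || i > n) return(0L)
    a <- max(a, 1L); b <- min(b, n)
    if (b < a) return(0L)
    rowc[i, b] - if (a > 1L) rowc[i, a - 1L] else 0L
  }
  ccount <- function(j, a, b) {            # |{x in [a,b]: bp(x, j), x < j}|
    if (b < a || j < 1L || j > n) return(0L)
    a <- max(a, 1L); b <- min(b, n)
    if (b < a) return(0L)
    colc[b, j] - if (a > 1L) colc[a - 1L, j] else 0L
  }
  # 2D prefix: S2[x, y] = |{(u, v): u <= x, v <= y, bp(u, v)}|
  S2 <- apply(rowc, 2L, cumsum)
  rect <- function(x1, x2, y1, y2) {       # pairs with u in [x1,x2], v in [y1,y2]
    if (x2 < x1 || y2 < y1) return(0L)
    x1 <- max(x1, 1L); y1 <- max(y1, 1L); x2 <- min(x2, n); y2 <- min(y2, n)
    if (x2 < x1 || y2 < y1) return(0L)
    g <- function(x, y) if (x < 1L || y < 1L) 0L else S2[x, y]
    g(x2, y2) - g(x1 - 1L, y2) - g(x2, y1 - 1L) + g(x1 - 1L, y1 - 1L)
  }
  arc1a <- function(i, j) rect(i, j, i, j)
  arc1b <- function(i, j) rcount(i, i + theta + 1L, j - 1L)
  arc1c <- function(i, j) ccount(j, i + 1L, j - theta - 1L)
  arc2a <- function(i, j, l, r) rect(i + 1L, l - 1L, r + 1L, j - 1L)
  arc2b <- function(i, j, l, r) {
    rcount(i, r + 1L, j - 1L) + rcount(i, i + theta + 1L, l - 1L) +  # (i,j) shifts
      rcount(l, r + 1L, j - 1L) + ccount(l, i + 1L, l - theta - 1L)  # (l,r) shifts
  }
  arc2c <- function(i, j, l, r) {
    ccount(j, i + 1L, l - 1L) + ccount(j, r + 1L, j - theta - 1L) +
      ccount(r, i + 1L, l - 1L) + rcount(r, r + theta + 1L, j - 1L)
  }
  arc2 <- function(i, j, l, r) arc2a(i, j, l, r) + arc2b(i, j, l, r) +
    arc2c(i, j, l, r)
  arc3 <- function(i, j, l, r) arc1a(i + 1L, l - 1L) + arc1a(r + 1L, j - 1L) +
    arc2(i, j, l, r)
  arc4 <- function(i, j, k) rcount(i, max(j + 1L, i + theta + 1L), k)
  arc5 <- function(i, j, k) rcount(j, j + theta + 1L, k)
  list(arc1a = arc1a, arc1b = arc1b, arc1c = arc1c, arc2a = arc2a,
       arc2b = arc2b, arc2c = arc2c, arc2 = arc2, arc3 = arc3,
       arc4 = arc4, arc5 = arc5)
}

#' McCaskill partition functions
#'
#' Interval partition functions of the dangle-free nearest-neighbour model:
#' `Z[i,j]` over all structures of `a[i..j]`, `ZB` over structures containing
#' the pair (i, j), and the multiloop assemblies `ZM` (at least one
#' component) and `ZM1` (exactly one component, left end paired).
#'
#' @param seq An `rna_seq` or string.
#' @param params A [turner_parameters()] object.
#' @return Object of class `turner_tables` with triangular matrices `Z`,
#'   `ZB`, `ZM`, `ZM1` (column index `j + 1`).
#' @examples
#' pf <- mccaskill_partition("GGGGCCC", turner_parameters("zero"))
#' pf$Z[1, 8]  # = 8 structures at zero energy
#' @export
mccaskill_partition <- function(seq, params = turner_parameters()) {
  seq <- parse_sequence(seq)
  tb <- turner_fill(seq, params, want_q = FALSE)
  structure(tb, class = "turner_tables")
}

# Shared fill routine for partition functions and neighbor-weighted sums.
turner_fill <- function(seq, params, want_q = TRUE) {
  n <- seq$n
  theta <- 3L
  rule <- pairing_rule("wc_wobble", theta)
  B <- bp_matrix(seq, rule)
  bpc <- vapply(1:4, function(cc) bp_with_code(seq, cc, rule), logical(n))
  rt <- params$rt
  arcs <- arc_counts(seq, rule)
  eb <- exp(-params$ml_b / rt)
  # closing decomposition: a + b for the closing pair, plus b for the last
  # component (whose ZM1 factor carries no branch term of its own)
  eab <- exp(-(params$ml_a + 2 * params$ml_b) / rt)
  ec <- exp(-params$ml_c / rt)
  jx <- function(j) j + 1L

  Z <- matrix(1, n + 1L, n + 1L)
  ZB <- matrix(0, n + 1L, n + 1L)
  ZM <- matrix(0, n + 1L, n + 1L)
  ZM1 <- matrix(0, n + 1L, n + 1L)
  if (want_q) {
    QB <- list(ms1 = matrix(0, n + 1L, n + 1L), ms2 = matrix(0, n + 1L, n + 1L))
    QM <- list(ms1 = matrix(0, n + 1L, n + 1L), ms2 = matrix(0, n + 1L, n + 1L))
    QM1 <- list(ms1 = matrix(0, n + 1L, n + 1L), ms2 = matrix(0, n + 1L, n + 1L))
    # row-1 auxiliaries (exterior-level decompositions)
    EL <- matrix(0, n + 1L, 4L); ER <- matrix(0, n + 1L, 4L)
    ERp <- matrix(0, n + 1L, 4L)
    FF <- array(0, c(n + 1L, 4L, n + 2L))   # F[jx(j), c, x+1] on [1, j]
    GG <- array(0, c(n + 1L, 4L, n + 2L))
    Q <- list(ms1 = numeric(n + 1L), ms2 = numeric(n + 1L))
    FF[jx(0L), , 1L] <- 1
    for (cc in 1:4) FF[jx(1L), cc, 1L + bpc[1L, cc]] <- 1
    if (n >= 2L) {
      for (j in 2L:min(theta + 1L, n)) {
        for (cc in 1:4) {
          if (bpc[j, cc]) {
            FF[jx(j), cc, 2:(n + 2L)] <- FF[jx(j - 1L), cc, 1:(n + 1L)]
          } else {
            FF[jx(j), cc, ] <- FF[jx(j - 1L), cc, ]
          }
        }
      }
    }
  }

  if (n >= theta + 2L) {
    for (d in (theta + 1L):(n - 1L)) {
      for (i in 1:(n - d)) {
        j <- i + d
        # --- ZB / QB ---
        if (B[i, j]) {
          hp <- exp(-hairpin_energy(params, seq, i, j) / rt)
          zb <- hp
          if (want_q) {
            qb1 <- hp * (1 + arcs$arc1a(i + 1L, j - 1L))
            qb2 <- hp * (1 + arcs$arc1a(i + 1L, j - 1L) +
                           arcs$arc1b(i, j) + arcs$arc1c(i, j))
          }
          lmax <- min(i + 1L + params$max_loop, j - theta - 2L)
          if (lmax >= i + 1L) {
            for (l in (i + 1L):lmax) {
              rmin <- max(l + theta + 1L, j - 1L - params$max_loop)
              if (rmin > j - 1L) next
              for (r in rmin:(j - 1L)) {
                if (ZB[l, jx(r)] == 0) next
                w <- exp(-interior_energy(params, seq, i, j, l, r) / rt)
                if (w == 0) next
                zb <- zb + w * ZB[l, jx(r)]
                if (want_q) {
                  a2 <- arcs$arc2a(i, j, l, r)
                  a3base <- arcs$arc1a(i + 1L, l - 1L) +
                    arcs$arc1a(r + 1L, j - 1L)
                  qb1 <- qb1 + w * (ZB[l, jx(r)] * (1 + a3base + a2) +
                                      QB$ms1[l, jx(r)])
                  qb2 <- qb2 + w * (ZB[l, jx(r)] *
                                      (1 + a3base + a2 + arcs$arc2b(i, j, l, r) +
                                         arcs$arc2c(i, j, l, r)) +
                                      QB$ms2[l, jx(r)])
                }
              }
            }
          }
          # multiloop closed by (i, j)
          if (j - theta - 2L >= i + theta + 3L) {
            for (r in (i + theta + 3L):(j - theta - 2L)) {
              zm <- ZM[i + 1L, jx(r - 1L)]; zm1 <- ZM1[r, jx(j - 1L)]
              if (zm == 0 || zm1 == 0) next
              zb <- zb + eab * zm * zm1
              if (want_q) {
                qb1 <- qb1 + eab * (zm * zm1 + QM$ms1[i + 1L, jx(r - 1L)] * zm1 +
                                      zm * QM1$ms1[r, jx(j - 1L)])
                qb2 <- qb2 + eab * (zm * zm1 + QM$ms2[i + 1L, jx(r - 1L)] * zm1 +
                                      zm * QM1$ms2[r, jx(j - 1L)])
              }
            }
          }
          ZB[i, jx(j)] <- zb
          if (want_q) { QB$ms1[i, jx(j)] <- qb1; QB$ms2[i, jx(j)] <- qb2 }
        }
        # --- ZM1 / QM1 ---
        zm1 <- 0
        if (want_q) { qm11 <- 0; qm12 <- 0 }
        for (k in (i + theta + 1L):j) {
          if (!B[i, k] || ZB[i, jx(k)] == 0) next
          w <- ec^(j - k)
          zm1 <- zm1 + w * ZB[i, jx(k)]
          if (want_q) {
            a1 <- arcs$arc1a(k + 1L, j)
            qm11 <- qm11 + w * (QB$ms1[i, jx(k)] + ZB[i, jx(k)] * a1)
            qm12 <- qm12 + w * (QB$ms2[i, jx(k)] +
                                  ZB[i, jx(k)] * (a1 + arcs$arc4(i, k, j) +
                                                    arcs$arc5(i, k, j)))
          }
        }
        ZM1[i, jx(j)] <- zm1
        if (want_q) { QM1$ms1[i, jx(j)] <- qm11; QM1$ms2[i, jx(j)] <- qm12 }
        # --- ZM / QM ---
        zm <- 0
        if (want_q) { qm1 <- 0; qm2 <- 0 }
        for (r in i:(j - theta - 1L)) {
          z1 <- ZM1[r, jx(j)]
          # single-component line (gap [i, r-1] fully unpaired)
          if (z1 > 0) {
            w <- eb * ec^(r - i)
            zm <- zm + w * z1
            if (want_q) {
              a1 <- arcs$arc1a(i, r - 1L)
              qm1 <- qm1 + w * (QM1$ms1[r, jx(j)] + z1 * a1)
              qm2 <- qm2 + w * (QM1$ms2[r, jx(j)] +
                                  z1 * (a1 + arcs$arc1c(i - 1L, r)))
            }
          }
          # >= 2 components: last starts at r
          if (r >= i + theta + 2L && z1 > 0 && ZM[i, jx(r - 1L)] > 0) {
            zm <- zm + eb * ZM[i, jx(r - 1L)] * z1
            if (want_q) {
              qm1 <- qm1 + eb * (QM$ms1[i, jx(r - 1L)] * z1 +
                                   ZM[i, jx(r - 1L)] * QM1$ms1[r, jx(j)])
              qm2 <- qm2 + eb * (QM$ms2[i, jx(r - 1L)] * z1 +
                                   ZM[i, jx(r - 1L)] * QM1$ms2[r, jx(j)])
            }
          }
        }
        ZM[i, jx(j)] <- zm
        if (want_q) { QM$ms1[i, jx(j)] <- qm1; QM$ms2[i, jx(j)] <- qm2 }
        # --- Z ---
        zacc <- Z[i, jx(j - 1L)]
        for (k in i:(j - theta - 1L)) {
          if (B[k, j] && ZB[k, jx(j)] > 0) {
            zacc <- zacc + Z[i, jx(k - 1L)] * ZB[k, jx(j)]
          }
        }
        Z[i, jx(j)] <- zacc
      }

      # --- row-1 auxiliaries and top-level Q at interval [1, j] ---
      if (want_q) {
        j <- 1L + d
        aj <- seq$codes[j]
        ks <- 1L:(j - theta - 1L)
        ks <- ks[B[ks, j]]
        for (cc in 1:4) {
          el <- EL[jx(j - 1L), cc]
          er <- ER[jx(j - 1L), cc]
          for (k in ks) {
            zbkj <- ZB[k, jx(j)]
            if (k == 1L) {
              el <- el + bpc[1L, cc] * zbkj
              er <- er + bpc[j, cc] * zbkj
            } else {
              el <- el + (EL[jx(k - 1L), cc] + bpc[k, cc] * Z[1L, jx(k - 1L)]) * zbkj
              er <- er + (ER[jx(k - 1L), cc] + bpc[j, cc] * Z[1L, jx(k - 1L)]) * zbkj
            }
          }
          EL[jx(j), cc] <- el
          ER[jx(j), cc] <- er
          # ERp
          v <- ER[jx(j - theta - 1L), cc]
          for (u in 1:theta) {
            m <- j - theta - 1L + u
            if (m - theta - 1L >= 2L) {
              for (k in 2L:(m - theta - 1L)) {
                if (B[k, m] && ZB[k, jx(m)] > 0) {
                  v <- v + ER[jx(k - 1L), cc] * ZB[k, jx(m)]
                }
              }
            }
          }
          ERp[jx(j), cc] <- v
          # F
          if (bpc[j, cc]) {
            fv <- c(0, FF[jx(j - 1L), cc, 1:(n + 1L)])
          } else {
            fv <- FF[jx(j - 1L), cc, ]
          }
          for (k in ks) {
            if (k == 1L) fv[1L] <- fv[1L] + ZB[k, jx(j)]
            else fv <- fv + FF[jx(k - 1L), cc, ] * ZB[k, jx(j)]
          }
          FF[jx(j), cc, ] <- fv
          # G
          gv <- FF[jx(j - theta - 1L), cc, ]
          for (u in 1:theta) {
            m <- j - theta - 1L + u
            if (m - theta - 1L < 1L) next
            for (k in 1L:(m - theta - 1L)) {
              if (!B[k, m] || ZB[k, jx(m)] == 0) next
              if (k == 1L) gv[1L] <- gv[1L] + ZB[k, jx(m)]
              else gv <- gv + FF[jx(k - 1L), cc, ] * ZB[k, jx(m)]
            }
          }
          GG[jx(j), cc, ] <- gv
        }
        # top-level Q
        add <- 0; q1in <- 0; q2in <- 0; cross <- 0
        for (k in ks) {
          zl <- Z[1L, jx(k - 1L)]; zbkj <- ZB[k, jx(j)]
          add <- add + zl * Z[k + 1L, jx(j - 1L)]
          q1in <- q1in + Q$ms1[jx(k - 1L)] * zbkj + zl * QB$ms1[k, jx(j)]
          q2in <- q2in + Q$ms2[jx(k - 1L)] * zbkj + zl * QB$ms2[k, jx(j)]
          xs <- 0:(n + 1L)
          fk <- if (k >= 2L) FF[jx(k - 1L), aj, ] else c(1, rep(0, n + 1L))
          gk <- GG[jx(k), seq$codes[k], ]
          cross <- cross + sum(xs * (fk + gk)) * zbkj
        }
        Q$ms1[jx(j)] <- Q$ms1[jx(j - 1L)] + add + q1in
        Q$ms2[jx(j)] <- Q$ms2[jx(j - 1L)] + add + q2in +
          EL[jx(j - 1L), aj] + ERp[jx(j), aj] + cross
      }
    }
  }

  out <- list(sequence = seq$string, params = params, n = n,
              Z = Z, ZB = ZB, ZM = ZM, ZM1 = ZM1)
  if (want_q) {
    out <- c(out, list(QB = QB, QM = QM, QM1 = QM1,
                       EL = EL, ER = ER, ERp = ERp, F = FF, G = GG,
                       Q_ms1 = Q$ms1, Q_ms2 = Q$ms2))
  }
  out
}

#' @export
print.turner_tables <- function(x, ...) {
  cat(sprintf("partition tables for %s ('%s'): Z = %.6g\n",
              x$sequence, x$params$id, x$Z[1L, x$n + 1L]))
  invisible(x)
}

#' Boltzmann-weighted total neighbor count Q
#'
#' Computes `Q_{1,n} = sum_s BF(s) N*(s)` for the chosen move set, where
#' `N*(s)` is the dynamic-program neighbor count (full MS1/MS2 except the
#' excluded multiloop moves; see the methods vignette), together with the
#' filled tables.
#'
#' @inheritParams mccaskill_partition
#' @param ms Move set.
#' @return List of class `turner_tables` with `Q` (scalar for the chosen
#'   move set) plus all tables.
#' @export
turner_Q <- function(seq, params = turner_parameters(),
                     ms = c("MS2", "MS1", "SHIFT_ONLY")) {
  ms <- match.arg(ms)
  seq <- parse_sequence(seq)
  tb <- turner_fill(seq, params, want_q = TRUE)
  q <- switch(ms, MS1 = tb$Q_ms1[seq$n + 1L], MS2 = tb$Q_ms2[seq$n + 1L],
              SHIFT_ONLY = tb$Q_ms2[seq$n + 1L] - tb$Q_ms1[seq$n + 1L])
  tb$Q <- q
  tb$moveset <- ms
  class(tb) <- "turner_tables"
  tb
}

#' Boltzmann expected network degree
#'
#' Expected number of dynamic-program-visible neighbors of a structure drawn
#' from the Boltzmann ensemble: `<N> = Q_{1,n} / Z_{1,n}`.
#'
#' @inheritParams turner_Q
#' @return List with `Q`, `Z`, `degree` and `normalized_degree`.
#' @examples
#' turner_expected_degree("GGGGCCC", turner_parameters("zero"), "MS2")$degree  # 4
#' @export
turner_expected_degree <- function(seq, params = turner_parameters(),
                                   ms = c("MS2", "MS1", "SHIFT_ONLY")) {
  ms <- match.arg(ms)
  seq <- parse_sequence(seq)
  tb <- turner_Q(seq, params, ms)
  Z <- tb$Z[1L, seq$n + 1L]
  list(Q = tb$Q, Z = Z, degree = tb$Q / Z,
       normalized_degree = tb$Q / Z / seq$n)
}
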