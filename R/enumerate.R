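# Exhaustive enumeration, move generation and network construction: the
# ground-truth oracle against which every dynamic program is checked.

#' Enumerate all secondary structures of a sequence
#'
#' Generates every structure satisfying the pairing rule (the empty structure
#' included), in a deterministic order: lexicographic on the sorted pair
#' list.  The number of structures grows roughly like 2.3^n, so enumeration
#' is guarded by a length cap.
#'
#' @param seq An `rna_seq` or string.
#' @param rule A [pairing_rule()].
#' @param max_n Enumeration cap (default 40 nt); exceeding it errors unless
#'   `force = TRUE`.
#' @param force Override the cap.
#' @return List of `secondary_structure` objects.
#' @examples
#' length(enumerate_structures("GGGGCCC"))       # 8
#' length(enumerate_structures("ACGUACGUACGU"))  # 35
#' @export
enumerate_structures <- function(seq, rule = pairing_rule(), max_n = 40L,
                                 force = FALSE) {
  seq <- parse_sequence(seq)
  if (seq$n > max_n && !force) {
    cond_stop("rnanetdeg_sequence_too_long",
              sprintf("sequence length %d exceeds enumeration cap %d (use force = TRUE to override)",
                      seq$n, max_n))
  }
  bpm <- bp_matrix(seq, rule)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (j - i <= rule$theta) return(list(matrix(integer(0), 0L, 2L)))
    key <- paste0(i, ",", j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    out <- rec(i + 1L, j)                     # i unpaired
    for (k in seq.int(i + 1L, j)) {
      if (!bpm[i, k]) next
      inner <- rec(i + 1L, k - 1L)
      rest <- if (k < j) rec(k + 1L, j) else list(matrix(integer(0), 0L, 2L))
      for (s1 in inner) for (s2 in rest) {
        out[[length(out) + 1L]] <- rbind(c(i, k), s1, s2)
      }
    }
    memo[[key]] <- out
    out
  }
  mats <- rec(1L, seq$n)
  keys <- vapply(mats, structure_key, "")
  mats <- mats[order(keys)]
  lapply(mats, new_structure, n = seq$n)
}

# All single moves applicable to structure s under move set `ms`.
# Returns an integer matrix with columns (kind, old_i, old_j, new_i, new_j);
# kind: 1 = addition, 2 = removal, 3 = shift.  With `restricted = TRUE` the
# move list excludes the multiloop moves that the Boltzmann-model dynamic
# program does not account for (see the methods vignette for the taxonomy).
structure_moves <- function(seq, s, ms = c("MS2", "MS1", "SHIFT_ONLY"),
                            rule = pairing_rule(), restricted = FALSE) {
  ms <- match.arg(ms)
  seq <- parse_sequence(seq)
  pm <- if (inherits(s, "secondary_structure")) s$pairs else as_pair_matrix(s)
  n <- seq$n
  bpm <- bp_matrix(seq, rule)
  ld <- loop_decomposition(pm, n)
  np <- nrow(pm)
  paired <- logical(n)
  if (np) paired[c(pm[, 1L], pm[, 2L])] <- TRUE
  free <- which(!paired)
  nkids <- lengths(ld$children)  # children count per loop (exterior first)

  out <- list()
  add_rows <- function(kind, oi, oj, ni, nj) {
    out[[length(out) + 1L]] <<- cbind(kind, oi, oj, ni, nj)
  }

  if (ms %in% c("MS2", "MS1")) {
    # removals
    if (np) add_rows(2L, pm[, 1L], pm[, 2L], NA_integer_, NA_integer_)
    # additions: both endpoints unpaired, same innermost loop, pairable
    if (length(free) >= 2L) {
      cand <- which(bpm[free, free, drop = FALSE], arr.ind = TRUE)
      if (nrow(cand)) {
        x <- free[cand[, 1L]]; y <- free[cand[, 2L]]
        keep <- ld$enc[x] == ld$enc[y]
        x <- x[keep]; y <- y[keep]
        if (restricted && length(x)) {
          drop <- logical(length(x))
          for (a in seq_along(x)) {
            l <- ld$enc[x[a]]
            if (l > 0L && nkids[l + 1L] >= 2L) {
              kids <- ld$children[[l + 1L]]
              drop[a] <- any(pm[kids, 1L] > x[a] & pm[kids, 2L] < y[a])
            }
          }
          x <- x[!drop]; y <- y[!drop]
        }
        if (length(x)) add_rows(1L, NA_integer_, NA_integer_, x, y)
      }
    }
  }

  if (ms %in% c("MS2", "SHIFT_ONLY") && np) {
    for (p in seq_len(np)) {
      pi1 <- pm[p, 1L]; pj1 <- pm[p, 2L]
      par <- ld$parent[p]
      # innermost enclosure after removing pair p
      enc2 <- ld$enc
      enc2[enc2 == p] <- par
      closes_multi <- nkids[p + 1L] >= 2L
      # loop containing p as a component
      in_multi <- par > 0L && nkids[par + 1L] >= 2L
      if (restricted && (closes_multi || in_multi)) {
        # gap bounds for the restricted taxonomy
        if (in_multi) {
          sibs <- ld$children[[par + 1L]]
          t_idx <- match(p, sibs)
          rgap_end <- if (t_idx < length(sibs)) pm[sibs[t_idx + 1L], 1L] - 1L
                      else pm[par, 2L] - 1L
          lgap_start <- if (t_idx > 1L) pm[sibs[t_idx - 1L], 2L] + 1L
                        else pm[par, 1L] + 1L
          first_comp <- t_idx == 1L
        }
      }
      for (e in c(pi1, pj1)) {
        for (z in free) {
          a <- min(e, z); b <- max(e, z)
          if (!bpm[a, b]) next
          ea <- if (a == e) par else enc2[a]
          eb <- if (b == e) par else enc2[b]
          if (ea != eb) next
          if (restricted) {
            inward <- a >= pi1 && b <= pj1   # new pair within [p, q]
            if (inward) {
              if (closes_multi) next
            } else if (in_multi) {
              if (e == pi1 && z > pj1) {            # (p, z): right extension
                if (z > rgap_end) next
              } else if (e == pj1 && z > pj1) {     # (q, z): right pivot
                if (z > rgap_end) next
              } else if (e == pi1 && z < pi1) {     # (z, p): left pivot
                if (!first_comp || z < lgap_start) next
              } else {                              # (z, q): left extension
                next
              }
            }
          }
          add_rows(3L, pi1, pj1, a, b)
        }
      }
    }
  }

  if (!length(out)) {
    m <- matrix(integer(0), 0L, 5L)
  } else {
    m <- do.call(rbind, out)
  }
  colnames(m) <- c("kind", "old_i", "old_j", "new_i", "new_j")
  m
}

#' Neighbors of a structure under a move set
#'
#' Applies every single move of the chosen move set (`MS1`: base-pair
#' addition/removal; `MS2`: additionally the four shift moves that re-anchor
#' one endpoint of an existing pair; `SHIFT_ONLY`: shifts only) and returns
#' the resulting valid structures.  Distinct moves always yield distinct
#' neighbors, so `length(neighbors(...))` is the network degree N(s).
#'
#' @inheritParams structure_moves
#' @param s A `secondary_structure` (validated for `seq`).
#' @return List with elements `move` (kind, removed pair, added pair) and
#'   `structure`.
#' @export
neighbors <- function(seq, s, ms = c("MS2", "MS1", "SHIFT_ONLY"),
                      rule = pairing_rule()) {
  ms <- match.arg(ms)
  seq <- parse_sequence(seq)
  if (!inherits(s, "secondary_structure")) s <- validate_structure(seq, s, rule)
  mv <- structure_moves(seq, s, ms, rule)
  pm <- s$pairs
  lapply(seq_len(nrow(mv)), function(r) {
    kind <- c("ADD", "REMOVE", "SHIFT")[mv[r, 1L]]
    pairs <- pm
    if (!is.na(mv[r, 2L])) {
      keep <- !(pairs[, 1L] == mv[r, 2L] & pairs[, 2L] == mv[r, 3L])
      pairs <- pairs[keep, , drop = FALSE]
    }
    if (!is.na(mv[r, 4L])) {
      pairs <- rbind(pairs, mv[r, 4:5])
    }
    list(move = list(kind = kind,
                     removed_pair = if (is.na(mv[r, 2L])) NULL else mv[r, 2:3],
                     added_pair = if (is.na(mv[r, 4L])) NULL else mv[r, 4:5]),
         structure = new_structure(pairs, seq$n))
  })
}

#' Count neighbors of a structure
#'
#' Degree N(s) of a structure in the move-set network, without materializing
#' the neighbor structures.  `restricted = TRUE` counts only the moves that
#' the Boltzmann-weighted dynamic program accounts for (all removals; all
#' additions except those enclosing a component of a multiloop; shifts except
#' the multiloop moves listed in the methods vignette).
#'
#' @inheritParams structure_moves
#' @return Integer count.
#' @export
count_neighbors <- function(seq, s, ms = c("MS2", "MS1", "SHIFT_ONLY"),
                            rule = pairing_rule(), restricted = FALSE) {
  nrow(structure_moves(seq, s, match.arg(ms), rule, restricted))
}

#' Build the full structure network of a sequence
#'
#' Nodes are all secondary structures of `seq` (deterministic enumeration
#' order); an undirected edge joins two structures differing by one move of
#' the move set, labeled with its move class.  Because every move is
#' reversible, the directed edge count equals twice the undirected count and
#' also equals the sum of degrees.
#'
#' @inheritParams enumerate_structures
#' @param ms Move set, see [neighbors()].
#' @return An object of class `structure_network`: list with `nodes`,
#'   `edges` (data frame: from, to, move_class), `directed_edge_count`,
#'   `degrees` (N(s) per node).
#' @examples
#' net <- build_network("GGGGCCC", "MS2")
#' nrow(net$edges)            # 16 undirected edges
#' net$directed_edge_count    # 32
#' @export
build_network <- function(seq, ms = c("MS2", "MS1", "SHIFT_ONLY"),
                          rule = pairing_rule(), max_n = 40L, force = FALSE) {
  ms <- match.arg(ms)
  seq <- parse_sequence(seq)
  nodes <- enumerate_structures(seq, rule, max_n, force)
  keys <- vapply(nodes, structure_key, "")
  idx <- stats::setNames(seq_along(nodes), keys)
  from <- integer(0); to <- integer(0); cls <- character(0)
  degrees <- integer(length(nodes))
  for (a in seq_along(nodes)) {
    nb <- neighbors(seq, nodes[[a]], ms, rule)
    degrees[a] <- length(nb)
    for (x in nb) {
      b <- idx[[structure_key(x$structure)]]
      if (is.null(b)) {
        cond_stop("rnanetdeg_internal",
                  "neighbor outside enumerated node set (internal error)")
      }
      if (a < b) {
        from <- c(from, a); to <- c(to, b)
        cls <- c(cls, if (x$move$kind == "SHIFT") "shift" else "addremove")
      }
    }
  }
  edges <- unique(data.frame(from = from, to = to, move_class = cls,
                             stringsAsFactors = FALSE))
  structure(list(sequence = seq$string, moveset = ms, nodes = nodes,
                 edges = edges, degrees = degrees,
                 directed_edge_count = sum(degrees)),
            class = "structure_network")
}

#' @export
print.structure_network <- function(x, ...) {
  cat(sprintf("structure network of %s (%s): %d nodes, %d undirected edges (%d directed)\n",
              x$sequence, x$moveset, length(x$nodes), nrow(x$edges),
              x$directed_edge_count))
  invisible(x)
}

#' Is a structure network connected?
#'
#' @param net A `structure_network`.
#' @return Logical; single-node networks are connected.
#' @export
network_is_connected <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = seq_along(net$nodes)))
  igraph::components(g)$no == 1L
}

#' Export a structure network as TSV tables
#'
#' Writes an edge list (`from_index`, `to_index`, `move_class`) and a node
#' table (`index`, `dot_bracket`).
#'
#' @param net A `structure_network`.
#' @param edge_file,node_file Output paths.
#' @export
write_network_tsv <- function(net, edge_file, node_file) {
  edges <- data.frame(from_index = net$edges$from, to_index = net$edges$to,
                      move_class = net$edges$move_class)
  utils::write.table(edges, edge_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  nodes <- data.frame(index = seq_along(net$nodes),
                      dot_bracket = vapply(net$nodes, write_dot_bracket, ""))
  utils::write.table(nodes, node_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(net)
}

#' Brute-force expected network degree
#'
#' Enumerates the full ensemble and computes `Q = sum w(s) N(s)`,
#' `Z = sum w(s)` and the expected degree `Q/Z`, with `w(s) = 1` (uniform)
#' or the Boltzmann factor `exp(-E(s)/RT)` when an energy function is given.
#' This is the enumeration oracle for all dynamic programs.
#'
#' @inheritParams build_network
#' @param energy_function Optional `function(structure) -> kcal/mol`.
#' @param rt Thermal energy RT in kcal/mol (default 37 C).
#' @param restricted Count only dynamic-program-visible moves (Boltzmann
#'   model comparison); see [count_neighbors()].
#' @return List with `Q`, `Z`, `degree`, `normalized_degree` and the
#'   per-structure degrees.
#' @export
brute_force_expected_degree <- function(seq, ms = c("MS2", "MS1", "SHIFT_ONLY"),
                                        rule = pairing_rule(),
                                        energy_function = NULL,
                                        rt = 0.00198717 * 310.15,
                                        restricted = FALSE,
                                        max_n = 40L, force = FALSE) {
  ms <- match.arg(ms)
  seq <- parse_sequence(seq)
  if (!is.null(energy_function) && seq$n > 25L && !force) {
    cond_stop("rnanetdeg_sequence_too_long",
              "energy-weighted enumeration capped at 25 nt (use force = TRUE)")
  }
  nodes <- enumerate_structures(seq, rule, max_n, force)
  degs <- vapply(nodes, function(s)
    count_neighbors(seq, s, ms, rule, restricted), 0L)
  w <- if (is.null(energy_function)) rep(1, length(nodes))
       else exp(-vapply(nodes, energy_function, 0) / rt)
  Q <- sum(w * degs)
  Z <- sum(w)
  list(Q = Q, Z = Z, degree = Q / Z, normalized_degree = Q / Z / seq$n,
       degrees = degs, weights = w)
}
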