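# Ensemble-level metrics built on exhaustive enumeration: degree
# distributions, 2D contact order, expected native contacts and
# conformational entropy — the order parameters used alongside the expected
# network degree in folding-kinetics correlation studies.

ensemble_weights <- function(seq, nodes, model, params) {
  if (model == "B") rep(1, length(nodes))
  else vapply(nodes, function(s)
    exp(-energy_of_structure(seq, s, params)$total / params$rt), 0)
}

#' Degree distribution of the structure ensemble
#'
#' Enumerates the ensemble, computes each structure's full neighbor count
#' N(s) under the chosen move set, and reports the (optionally
#' Boltzmann-weighted) distribution of N.  With an `energy_cutoff` only
#' structures within that many kcal/mol of the minimum energy enter the
#' histogram; `coverage` = Z*/Z reports the retained fraction of the
#' partition function.  Note that N(s) here is the unrestricted move count
#' (the `neighbor_counter` field records this), whereas the Boltzmann
#' dynamic program uses the restricted count; the two coincide on
#' multiloop-free ensembles.
#'
#' @param seq An `rna_seq` or string.
#' @param model `"B"` (uniform weights) or `"C"` (Boltzmann weights).
#' @param ms Move set.
#' @param params [turner_parameters()] for model C.
#' @param energy_cutoff Optional kcal/mol band above the minimum (model C).
#' @param rule A [pairing_rule()].
#' @param max_n Enumeration cap.
#' @return Object of class `degree_distribution`: `histogram` (data frame of
#'   degree and normalized weight), `mean`, `sd`, `coverage`,
#'   `normalization` (Z*), `Z`.
#' @examples
#' degree_distribution("GGGGCCC", "B", "MS2")$mean  # exactly 4
#' @export
degree_distribution <- function(seq, model = c("B", "C"),
                                ms = c("MS2", "MS1", "SHIFT_ONLY"),
                                params = turner_parameters(),
                                energy_cutoff = NULL,
                                rule = pairing_rule(), max_n = 40L) {
  model <- match.arg(model); ms <- match.arg(ms)
  seq <- parse_sequence(seq)
  nodes <- enumerate_structures(seq, rule, max_n)
  degs <- vapply(nodes, function(s) count_neighbors(seq, s, ms, rule), 0L)
  w <- ensemble_weights(seq, nodes, model, params)
  Z <- sum(w)
  keep <- rep(TRUE, length(nodes))
  if (!is.null(energy_cutoff)) {
    if (model == "B") {
      cond_stop("rnanetdeg_bad_argument",
                "energy_cutoff is only meaningful for model C")
    }
    en <- vapply(nodes, function(s) energy_of_structure(seq, s, params)$total, 0)
    keep <- en <= min(en) + energy_cutoff
  }
  zstar <- sum(w[keep])
  hw <- tapply(w[keep], degs[keep], sum) / zstar
  hist <- data.frame(degree = as.integer(names(hw)),
                     weight = as.numeric(hw))
  mu <- sum(w[keep] * degs[keep]) / zstar
  sdv <- sqrt(max(0, sum(w[keep] * degs[keep]^2) / zstar - mu^2))
  structure(list(sequence = seq$string, model = model, moveset = ms,
                 histogram = hist, mean = mu, sd = sdv,
                 coverage = zstar / Z, normalization = zstar, Z = Z,
                 neighbor_counter = "full"),
            class = "degree_distribution")
}

#' @export
print.degree_distribution <- function(x, ...) {
  cat(sprintf("degree distribution (%s, model %s) for %s: mean %.4f, sd %.4f, coverage %.4f\n",
              x$moveset, x$model, x$sequence, x$mean, x$sd, x$coverage))
  invisible(x)
}

#' 2D contact order of a secondary structure
#'
#' Absolute contact order is the mean chain separation of the base pairs,
#' `sum(j - i) / N` over the `N` pairs; relative contact order divides by the
#' sequence length.
#'
#' @param s A `secondary_structure`, or a pair matrix.
#' @param n Sequence length (taken from `s` when available).
#' @return List with `absolute` and `relative`.
#' @examples
#' contact_order(validate_structure("GGGGCCC", rbind(c(1, 7), c(2, 6))))
#' @export
contact_order <- function(s, n = NULL) {
  if (inherits(s, "secondary_structure")) { pm <- s$pairs; n <- s$n }
  else pm <- as_pair_matrix(s)
  if (!nrow(pm)) {
    cond_stop("rnanetdeg_empty_structure",
              "contact order undefined for the empty structure")
  }
  if (is.null(n)) cond_stop("rnanetdeg_bad_argument", "n required")
  absolute <- mean(pm[, 2L] - pm[, 1L])
  list(absolute = absolute, relative = absolute / n)
}

#' Expected number of native contacts
#'
#' `sum_{(i,j) in s0} p_{i,j}` where `p_{i,j}` is the (uniform or Boltzmann)
#' probability that pair (i, j) is present in the ensemble, computed by
#' exhaustive enumeration.
#'
#' @inheritParams degree_distribution
#' @param s0 Reference ("native") structure, validated against `seq`.
#' @return List with `expected_native_contacts`, `pair_probabilities`
#'   (data frame i, j, probability over the pairs of `s0`) and `n_native`.
#' @export
expected_native_contacts <- function(seq, s0, model = c("B", "C"),
                                     params = turner_parameters(),
                                     rule = pairing_rule(), max_n = 40L) {
  model <- match.arg(model)
  seq <- parse_sequence(seq)
  if (!inherits(s0, "secondary_structure")) s0 <- validate_structure(seq, s0, rule)
  nodes <- enumerate_structures(seq, rule, max_n)
  w <- ensemble_weights(seq, nodes, model, params)
  Z <- sum(w)
  pm0 <- s0$pairs
  probs <- numeric(nrow(pm0))
  if (nrow(pm0)) {
    for (r in seq_len(nrow(pm0))) {
      has <- vapply(nodes, function(s)
        any(s$pairs[, 1L] == pm0[r, 1L] & s$pairs[, 2L] == pm0[r, 2L]), TRUE)
      probs[r] <- sum(w[has]) / Z
    }
  }
  list(expected_native_contacts = sum(probs),
       pair_probabilities = data.frame(i = pm0[, 1L], j = pm0[, 2L],
                                       probability = probs),
       n_native = nrow(pm0))
}

#' Conformational entropy of the ensemble
#'
#' `-sum_s p(s) log p(s)` in units of the Boltzmann constant, with p uniform
#' (model B) or Boltzmann (model C), over the exhaustively enumerated
#' ensemble.
#'
#' @inheritParams degree_distribution
#' @return Numeric scalar (k_B units, natural log).
#' @examples
#' conformational_entropy("GGGGCCC", "B")  # log(8)
#' @export
conformational_entropy <- function(seq, model = c("B", "C"),
                                   params = turner_parameters(),
                                   rule = pairing_rule(), max_n = 40L) {
  model <- match.arg(model)
  seq <- parse_sequence(seq)
  nodes <- enumerate_structures(seq, rule, max_n)
  w <- ensemble_weights(seq, nodes, model, params)
  p <- w / sum(w)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Metric table and correlations for (sequence, structure) pairs
#'
#' Given a table with columns `id`, `sequence` and `dot_bracket` (a
#' reference structure per sequence), computes per-row order parameters:
#' uniform expected degrees (MS1, MS2), conformational entropy, absolute and
#' relative contact order of the reference structure, and the expected
#' number of native contacts with the reference as native.
#'
#' @param table Data frame with `id`, `sequence`, `dot_bracket`.
#' @param model `"B"` or `"C"` for entropy/native-contact weighting.
#' @param params [turner_parameters()] for model C.
#' @param max_n Enumeration cap for the enumeration-based columns.
#' @return Data frame of metrics, one row per input row.
#' @export
structure_metrics <- function(table, model = "B",
                              params = turner_parameters(), max_n = 40L) {
  stopifnot(all(c("id", "sequence", "dot_bracket") %in% names(table)))
  rows <- lapply(seq_len(nrow(table)), function(r) {
    s <- parse_sequence(table$sequence[r])
    s0 <- validate_structure(s, parse_dot_bracket(table$dot_bracket[r]))
    co <- if (nrow(s0$pairs)) contact_order(s0)
          else list(absolute = NA_real_, relative = NA_real_)
    data.frame(
      id = table$id[r],
      n = s$n,
      degree_ms1 = uniform_expected_degree(s, "MS1")$degree,
      degree_ms2 = uniform_expected_degree(s, "MS2")$degree,
      entropy = conformational_entropy(s, model, params, max_n = max_n),
      contact_order_abs = co$absolute,
      contact_order_rel = co$relative,
      native_contacts = expected_native_contacts(
        s, s0, model, params, max_n = max_n)$expected_native_contacts)
  })
  do.call(rbind, rows)
}

#' @rdname structure_metrics
#' @param metrics A data frame as returned by [structure_metrics()].
#' @return For `metric_correlations`: the Pearson correlation matrix of the
#'   numeric metric columns.
#' @export
metric_correlations <- function(metrics) {
  num <- metrics[, setdiff(names(metrics), c("id", "n")), drop = FALSE]
  stats::cor(num, use = "pairwise.complete.obs", method = "pearson")
}
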