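# Nearest-neighbour energy model, dangles off: hairpin initiation, interior
# loops (stacks, bulges, proper interior loops) and affine multiloops
# a + b*N_branches + c*N_unpaired.  Exterior (unconstrained) bases contribute
# nothing.  The single energy routine per loop type is shared between the
# structure evaluator and the partition-function recursions, so dynamic
# program and enumeration oracle always see the same model.

# pair type codes follow the Vienna convention: CG=1, GC=2, GU=3, UG=4,
# AU=5, UA=6 (0 = not pairable)
#' Nearest-neighbour energy parameters
#'
#' Builds a parameter set for the dangle-free nearest-neighbour model.
#' `"zero"` maps every energy term to 0 (the Boltzmann model then reduces
#' exactly to the uniform counting model); `"builtin_minimal"` is a compact,
#' fully specified set shipped with the package (sequence-dependent stacking
#' for the six pairable dinucleotide combinations, logarithmic
#' hairpin/bulge/interior initiation, a small terminal AU/GU penalty on
#' hairpin-closing pairs, and affine multiloop constants); a file path is
#' read as a Vienna-dialect parameter file via [read_vienna_parameters()].
#'
#' @param source `"zero"`, `"builtin_minimal"`, or a parameter file path.
#' @param temperature Temperature in Celsius (default 37).
#' @param max_loop Maximum number of unpaired nucleotides in a bulge or
#'   interior loop (jointly over both sides); structures exceeding it are
#'   excluded from the ensemble.  Default 30 (`Inf` for `"zero"`).
#' @return Object of class `turner_params`.
#' @export
turner_parameters <- function(source = "builtin_minimal", temperature = 37,
                              max_loop = NULL) {
  rt <- R_GAS * (temperature + 273.15)
  if (length(source) == 1L && source %in% c("zero", "builtin_minimal")) {
    if (source == "zero") {
      if (is.null(max_loop)) max_loop <- Inf
      p <- list(
        id = "zero", rt = rt, temperature = temperature, max_loop = max_loop,
        stack = matrix(0, 6, 6, dimnames = list(PAIR_NAMES, PAIR_NAMES)),
        hairpin = rep(0, 31), bulge = rep(0, 31), internal = rep(0, 31),
        hairpin_extrap = 0, loop_extrap = 0,
        ninio = 0, ninio_max = 0, terminal_au = 0,
        ml_a = 0, ml_b = 0, ml_c = 0)
    } else {
      if (is.null(max_loop)) max_loop <- 30
      # pair "strength" CG/GC 3, AU/UA 2, GU/UG 1 drives the stack table
      strength <- c(CG = 3, GC = 3, GU = 1, UG = 1, AU = 2, UA = 2)
      st <- matrix(0, 6, 6, dimnames = list(PAIR_NAMES, PAIR_NAMES))
      for (a in 1:6) for (b in 1:6) {
        st[a, b] <- -(0.6 + 0.35 * (strength[a] + strength[b])) +
          0.05 * ((a * 7L + b * 3L) %% 5L)  # mild, deterministic asymmetry
      }
      sz <- 1:31
      p <- list(
        id = "builtin_minimal", rt = rt, temperature = temperature,
        max_loop = max_loop,
        stack = st,
        hairpin = c(Inf, Inf, 5.4 + 1.08 * log(sz[-(1:2)] / 3)),
        bulge = 3.8 + 1.08 * log(sz),
        internal = c(Inf, 4.0 + 1.08 * log(sz[-1] / 2)),
        hairpin_extrap = 1.08, loop_extrap = 1.08,
        ninio = 0.5, ninio_max = 3.0, terminal_au = 0.5,
        ml_a = 3.4, ml_b = 0.4, ml_c = 0.1)
    }
    class(p) <- "turner_params"
    return(p)
  }
  read_vienna_parameters(source, temperature = temperature,
                         max_loop = if (is.null(max_loop)) 30 else max_loop)
}

#' @export
print.turner_params <- function(x, ...) {
  cat(sprintf("nearest-neighbour parameters '%s': T = %g C (RT = %.4f kcal/mol), ML (a,b,c) = (%g, %g, %g), loop cap %s\n",
              x$id, x$temperature, x$rt, x$ml_a, x$ml_b, x$ml_c,
              format(x$max_loop)))
  invisible(x)
}

pair_type <- function(seq, i, j) PAIR_TYPE[cbind(seq$codes[i], seq$codes[j])]

loop_size_energy <- function(tab, extrap, size) {
  if (size < 1) return(Inf)
  if (size <= length(tab)) tab[size]
  else tab[length(tab)] + extrap * 1.75 * log(size / length(tab))
}

# hairpin closed by (i, j)
hairpin_energy <- function(params, seq, i, j) {
  size <- j - i - 1L
  e <- loop_size_energy(params$hairpin, params$hairpin_extrap, size)
  t <- pair_type(seq, i, j)
  if (t >= 3L) e <- e + params$terminal_au     # AU/UA/GU/UG closing
  e
}

# interior loop (stack, bulge or proper interior loop) between closing pair
# (i, j) and interior pair (l, r), i < l < r < j
interior_energy <- function(params, seq, i, j, l, r) {
  g1 <- l - i - 1L; g2 <- j - r - 1L
  if (g1 + g2 > params$max_loop) return(Inf)
  t1 <- pair_type(seq, i, j)
  t2 <- pair_type(seq, r, l)                   # interior pair reversed
  if (t1 == 0L || t2 == 0L) return(Inf)
  if (g1 == 0L && g2 == 0L) return(params$stack[t1, t2])
  if (g1 == 0L || g2 == 0L) {
    e <- loop_size_energy(params$bulge, params$loop_extrap, g1 + g2)
    if (g1 + g2 == 1L) e <- e + params$stack[t1, t2]   # size-1 bulge stacks
    return(e)
  }
  e <- loop_size_energy(params$internal, params$loop_extrap, g1 + g2)
  e + min(params$ninio_max, params$ninio * abs(g1 - g2))
}

multiloop_energy <- function(params, n_branches, n_unpaired) {
  # n_branches counts interior components; the closing pair adds one branch
  params$ml_a + params$ml_b * (n_branches + 1) + params$ml_c * n_unpaired
}

#' Free energy of a secondary structure
#'
#' Decomposes a structure into loops (hairpins, interior loops including
#' stacks and bulges, affine multiloops; the exterior contributes 0) and sums
#' their energies under the given parameter set.  This evaluator shares the
#' per-loop energy routines with the partition-function recursions and is
#' the energy oracle for brute-force Boltzmann sums.
#'
#' @param seq An `rna_seq` or string.
#' @param s A `secondary_structure` or pair set.
#' @param params A [turner_parameters()] object.
#' @return List of class `energy_evaluation`: `total` (kcal/mol; `Inf` for
#'   ensemble-excluded structures such as over-long interior loops) and
#'   `loops` (data frame of loop kind, closing pair and energy).
#' @examples
#' p <- turner_parameters("builtin_minimal")
#' energy_of_structure("GGGGCCC", rbind(c(1, 7), c(2, 6)), p)$total
#' @export
energy_of_structure <- function(seq, s, params = turner_parameters()) {
  seq <- parse_sequence(seq)
  if (!inherits(s, "secondary_structure")) s <- validate_structure(seq, s)
  pm <- s$pairs
  np <- nrow(pm)
  if (!np) {
    return(structure(list(total = 0,
                          loops = data.frame(kind = character(0), i = integer(0),
                                             j = integer(0), energy = numeric(0))),
                     class = "energy_evaluation"))
  }
  ld <- loop_decomposition(pm, seq$n)
  kind <- character(np); en <- numeric(np)
  for (p in seq_len(np)) {
    kids <- ld$children[[p + 1L]]
    i <- pm[p, 1L]; j <- pm[p, 2L]
    if (length(kids) == 0L) {
      kind[p] <- "hairpin"
      en[p] <- hairpin_energy(params, seq, i, j)
    } else if (length(kids) == 1L) {
      l <- pm[kids, 1L]; r <- pm[kids, 2L]
      kind[p] <- if (l == i + 1L && r == j - 1L) "stack"
                 else if (l == i + 1L || r == j - 1L) "bulge"
                 else "interior"
      en[p] <- interior_energy(params, seq, i, j, l, r)
    } else {
      kind[p] <- "multiloop"
      nu <- (j - i - 1L) - sum(pm[kids, 2L] - pm[kids, 1L] + 1L)
      en[p] <- multiloop_energy(params, length(kids), nu)
    }
  }
  structure(list(total = sum(en),
                 loops = data.frame(kind = kind, i = pm[, 1L], j = pm[, 2L],
                                    energy = en)),
            class = "energy_evaluation")
}

#' @export
print.energy_evaluation <- function(x, ...) {
  cat(sprintf("free energy %.3f kcal/mol over %d loops\n",
              x$total, nrow(x$loops)))
  invisible(x)
}

#' Read a Vienna-dialect nearest-neighbour parameter file
#'
#' Parses the sections this model uses — `stack`, `hairpin`, `bulge`,
#' `interior`, `NINIO`, `ML_params` and `Misc` (terminal AU) — from a file in
#' the Vienna RNA parameter dialect (energies in dcal/mol; `INF` allowed).
#' Mismatch and dangle tables are ignored: the model is dangle-free.
#'
#' @param path File path.
#' @inheritParams turner_parameters
#' @return A `turner_params` object.
#' @export
read_vienna_parameters <- function(path, temperature = 37, max_loop = 30) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("/\\*.*?\\*/", "", lines)
  sec_at <- grep("^# ", lines)
  secs <- list()
  for (si in seq_along(sec_at)) {
    nm <- trimws(sub("^# ", "", lines[sec_at[si]]))
    to <- if (si < length(sec_at)) sec_at[si + 1L] - 1L else length(lines)
    body <- lines[(sec_at[si] + 1L):to]
    toks <- unlist(strsplit(paste(body, collapse = " "), "[[:space:]]+"))
    toks <- toks[nzchar(toks)]
    vals <- suppressWarnings(as.numeric(ifelse(toks %in% c("INF", "inf"),
                                               Inf, toks)))
    secs[[nm]] <- vals[!is.na(vals)]
  }
  need <- c("stack", "hairpin", "bulge", "interior", "ML_params")
  miss <- setdiff(need, names(secs))
  if (length(miss)) {
    cond_stop("rnanetdeg_missing_table",
              sprintf("parameter file lacks required table(s): %s",
                      paste(miss, collapse = ", ")))
  }
  stv <- secs[["stack"]]
  # Vienna stack tables are 7x7 (pair types + N); keep the leading 6x6
  st <- matrix(0, 6, 6, dimnames = list(PAIR_NAMES, PAIR_NAMES))
  if (length(stv) >= 49) {
    m7 <- matrix(stv[1:49], 7, 7, byrow = TRUE)
    st[] <- m7[1:6, 1:6] / 100
  } else if (length(stv) >= 36) {
    st[] <- matrix(stv[1:36], 6, 6, byrow = TRUE) / 100
  } else {
    cond_stop("rnanetdeg_missing_table", "stack table too short")
  }
  takeloop <- function(v) {
    v <- v / 100
    # Vienna loop tables start at size 0
    out <- v[seq_len(min(length(v), 31L))]
    if (length(out) < 31L) out <- c(out, rep(out[length(out)], 31L - length(out)))
    out[-1L]  # sizes 1..30
  }
  hp <- c(takeloop(secs[["hairpin"]]), Inf)[1:31]
  bu <- c(takeloop(secs[["bulge"]]), Inf)[1:31]
  il <- c(takeloop(secs[["interior"]]), Inf)[1:31]
  ml <- secs[["ML_params"]] / 100
  ninio <- if (!is.null(secs[["NINIO"]])) secs[["NINIO"]] / 100 else c(0, 0, 0)
  term_au <- 0
  if (!is.null(secs[["Misc"]]) && length(secs[["Misc"]]) >= 3) {
    term_au <- secs[["Misc"]][3] / 100
  }
  p <- list(id = basename(path), rt = R_GAS * (temperature + 273.15),
            temperature = temperature, max_loop = max_loop,
            stack = st, hairpin = hp, bulge = bu, internal = il,
            hairpin_extrap = 1.079, loop_extrap = 1.079,
            ninio = ninio[1], ninio_max = if (length(ninio) >= 3) ninio[3] else Inf,
            terminal_au = term_au,
            # Vienna ML_params order: unpaired, closing, intern(branch)
            ml_c = ml[1], ml_a = ml[2], ml_b = if (length(ml) >= 3) ml[3] else 0)
  class(p) <- "turner_params"
  p
}

#' Write parameters in the Vienna dialect (round-trip serializer)
#'
#' @param params A `turner_params` object.
#' @param path Output file path.
#' @export
write_vienna_parameters <- function(params, path) {
  fmt <- function(x) {
    ifelse(is.finite(x), format(round(x * 100)), "INF")
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines("## RNAfold parameter file v2.0", con)
  writeLines("# stack", con)
  m7 <- matrix(Inf, 7, 7); m7[1:6, 1:6] <- params$stack
  utils::write.table(matrix(fmt(m7), 7, 7), con, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  for (nm in c("hairpin", "bulge", "interior")) {
    tab <- switch(nm, hairpin = params$hairpin, bulge = params$bulge,
                  interior = params$internal)
    writeLines(paste0("# ", nm), con)
    writeLines(paste(fmt(c(Inf, tab[1:30])), collapse = " "), con)
  }
  writeLines("# NINIO", con)
  writeLines(paste(fmt(c(params$ninio, 0, params$ninio_max)), collapse = " "), con)
  writeLines("# Misc", con)
  writeLines(paste(fmt(c(0, 0, params$terminal_au)), collapse = " "), con)
  writeLines("# ML_params", con)
  writeLines(paste(fmt(c(params$ml_c, params$ml_a, params$ml_b)), collapse = " "), con)
  writeLines("# END", con)
  invisible(params)
}
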