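# Shared constants and condition helpers (loaded first by collation).

RNA_ALPHABET <- c("A", "C", "G", "U")

# Watson-Crick + wobble pairing table, indexed by nucleotide codes 1..4
# (A=1, C=2, G=3, U=4): AU, UA, CG, GC, GU, UG.
WC_WOBBLE <- {
  m <- matrix(FALSE, 4, 4, dimnames = list(RNA_ALPHABET, RNA_ALPHABET))
  m["A", "U"] <- m["U", "A"] <- TRUE
  m["C", "G"] <- m["G", "C"] <- TRUE
  m["G", "U"] <- m["U", "G"] <- TRUE
  m
}

cond_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "rnanetdeg_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}


PAIR_TYPE <- {
  m <- matrix(0L, 4, 4, dimnames = list(RNA_ALPHABET, RNA_ALPHABET))
  m["C", "G"] <- 1L; m["G", "C"] <- 2L; m["G", "U"] <- 3L
  m["U", "G"] <- 4L; m["A", "U"] <- 5L; m["U", "A"] <- 6L
  m
}
PAIR_NAMES <- c("CG", "GC", "GU", "UG", "AU", "UA")

R_GAS <- 0.00198717  # kcal / (mol K)

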