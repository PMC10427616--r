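## Shared constants and small helpers.

# 20 standard amino acids, one-letter, fixed order used everywhere
AA1 <- c("A","C","D","E","F","G","H","I","K","L",
         "M","N","P","Q","R","S","T","V","W","Y")

AA3 <- c(A="ALA",C="CYS",D="ASP",E="GLU",F="PHE",G="GLY",H="HIS",I="ILE",
         K="LYS",L="LEU",M="MET",N="ASN",P="PRO",Q="GLN",R="ARG",S="SER",
         T="THR",V="VAL",W="TRP",Y="TYR")

AA3TO1 <- structure(names(AA3), names = unname(AA3))

# van der Waals radii (Angstrom) by element; default used with a warning
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)
VDW_DEFAULT <- 1.70

# Theoretical maximum accessible surface areas (Angstrom^2) per residue in a
# Gly-X-Gly tripeptide (Tien et al. 2013, "theoretical" column); reference
# for relative SASA.
MAX_ASA <- c(A = 129.0, C = 167.0, D = 193.0, E = 223.0, F = 240.0,
             G = 104.0, H = 224.0, I = 197.0, K = 236.0, L = 201.0,
             M = 224.0, N = 195.0, P = 159.0, Q = 225.0, R = 274.0,
             S = 155.0, T = 172.0, V = 174.0, W = 285.0, Y = 263.0)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Seed helper: derive a stream of child seeds from one master seed
#'
#' Keeps every derived seed strictly below 2^31 so it is a valid R integer.
#' @param seed master seed (integer).
#' @param n number of child seeds.
#' @return integer vector of length n.
#' @keywords internal
deriveSeeds <- function(seed, n) {
  # LCG on 31-bit range; deterministic, independent of R's RNG state
  s <- as.double(seed %% 2147483647L)
  out <- integer(n)
  for (i in seq_len(n)) {
    s <- (s * 48271) %% 2147483647
    out[i] <- as.integer(s)
  }
  out
}

# Run expr with a local RNG state seeded at `seed`, restoring the caller's
# RNG afterwards.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
}
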