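# Internal constants and helpers shared across modules.

# Canonical 20-residue alphabet, alphabetical one-letter codes.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Padding symbol used when a sequence window runs past a protein or peptide end.
PAD_SYMBOL <- "_"

# Phospho-acceptor residues.
ACCEPTOR_RESIDUES <- c("S", "T", "Y")

# Approximate human proteome residue frequencies (rounded averages),
# renormalized to sum to 1; the default background composition.
HUMAN_AA_FREQ <- local({
  f <- c(A = 0.070, C = 0.023, D = 0.047, E = 0.071, F = 0.037, G = 0.066,
         H = 0.026, I = 0.043, K = 0.057, L = 0.100, M = 0.021, N = 0.036,
         P = 0.063, Q = 0.048, R = 0.056, S = 0.083, T = 0.054, V = 0.060,
         W = 0.012, Y = 0.027)
  f / sum(f)
})

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

# Modular multiplication that stays exact in double precision (m < 2^31).
mulmod <- function(a, b, m) {
  a <- a %% m
  b <- b %% m
  hi <- floor(a / 65536)
  lo <- a %% 65536
  (((hi * b) %% m) * 65536 + lo * b) %% m
}

#' Derive a substream seed from a master seed
#'
#' All randomness in the package flows from one integer master seed; each
#' logical stage draws from its own substream so that, e.g., changing the
#' number of proteins does not perturb downstream reporter-ion noise. The
#' derivation is a fixed multiplicative hash modulo the Mersenne prime
#' 2^31 - 1, so derived seeds are always valid 32-bit R seeds.
#'
#' @param master integer master seed.
#' @param stream integer substream index (>= 0).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stream) {
  m <- 2147483647
  s <- (mulmod(abs(as.double(master)) + 1, 2654435761 %% m, m) +
          mulmod(abs(as.double(stream)) + 1, 97781, m)) %% m
  as.integer(s %% 2147483645) + 1L
}

# FNV-1a 32-bit hash of a string, returned as 8 hex characters. Used for
# config fingerprints in run manifests (no cryptographic intent).
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h <- mulmod(h, 16777619, 2^32)
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Split a character vector of equal-length windows into a character matrix
# (one row per window, one column per position).
window_matrix <- function(windows) {
  n <- length(windows)
  if (n == 0L) stop_input("no windows supplied")
  L <- unique(nchar(windows))
  if (length(L) != 1L) stop_input("windows must all have the same width")
  matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
         nrow = n, ncol = L, byrow = TRUE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
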