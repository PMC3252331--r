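## Internal helpers shared across modules.

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so seeded simulations never perturb global randomness.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Split an aligned/unaligned sequence string into single characters.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Encode A/C/G/T as 1..4; every other character (gaps, N, ?, other IUPAC
# ambiguity codes) becomes NA and is treated as missing downstream.
BASES <- c(A = 1L, C = 2L, G = 3L, T = 4L)

encode_base <- function(chars) {
  out <- BASES[chars]
  names(out) <- NULL
  unname(out)
}

# n x L integer matrix (NA = missing) from a character vector of sequences.
encode_matrix <- function(seqs) {
  stopifnot(length(seqs) >= 1L)
  L <- nchar(seqs[1L])
  m <- matrix(NA_integer_, nrow = length(seqs), ncol = L)
  for (i in seq_along(seqs)) {
    ch <- seq_chars(seqs[i])
    if (length(ch) != L) stop("sequences have unequal lengths")
    m[i, ] <- encode_base(ch)
  }
  rownames(m) <- names(seqs)
  m
}

# genus = first whitespace/underscore-delimited token of the binomial
genus_of <- function(species) {
  vapply(strsplit(species, "[ _]+"), `[[`, character(1), 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
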