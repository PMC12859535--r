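# Internal helpers: bitmask set algebra over small universes, seeded evaluation.

# popcount lookup for all masks over a w-bit universe
popcount_table <- function(w) {
  stopifnot(w >= 0, w <= 25)
  n <- bitwShiftL(1L, w)
  pc <- integer(n)
  if (w == 0L) return(pc)
  for (b in 0:(w - 1L)) {
    bit <- bitwShiftL(1L, b)
    pc <- pc + as.integer(bitwAnd(seq_len(n) - 1L, bit) != 0L)
  }
  pc
}

mask_of <- function(idx) {
  if (length(idx) == 0L) return(0L)
  sum(bitwShiftL(1L, as.integer(idx) - 1L))
}

idx_of <- function(mask, w) {
  which(bitwAnd(mask, bitwShiftL(1L, 0:(w - 1L))) != 0L)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream; seed = NULL uses the current stream.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
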