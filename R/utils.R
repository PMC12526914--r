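# internal helpers

# Evaluate `code` under `set.seed(seed)` and restore the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derivation: keeps derived seeds < 2^31 and spreads
# (seed, index) pairs apart without colliding for small indices.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.numeric(seed) %% 2147483647
  for (i in idx) {
    s <- (s * 48271 + as.numeric(i) + 1) %% 2147483647
  }
  as.integer(s)
}
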