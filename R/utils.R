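# Small internal helpers.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards, so library internals never perturb user
# randomness.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(expr)
}

# derive a stage sub-seed from a master seed, kept within 32-bit range
.subSeed <- function(seed, k) {
  as.integer((as.double(seed) * 113 + as.double(k) * 7919) %% 2147483647)
}
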