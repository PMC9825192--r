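# Internal RNG helpers: every stochastic entry point takes an explicit seed
# and restores the caller's RNG state, so adding one call never perturbs
# another's stream.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Stable small-integer seed derived from a master seed and a label, so each
# simulated artifact gets its own reproducible stream (< 2^31).
derive_seed <- function(seed, label) {
  h <- 0
  for (v in utf8ToInt(label)) h <- (h * 131 + v) %% 1000003L
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587)
}
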