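## Deterministic per-entity RNG substreams.
##
## Every source of randomness derives its seed from a root seed plus entity
## identifiers, so adding participants or sessions never reshuffles the
## draws of existing ones.

# integer code of an identifier string, stable across platforms
idCode <- function(s) {
  v <- utf8ToInt(s)
  sum(v * seq_along(v)) %% 2147483647
}

# combine a root seed and entity keys into a 31-bit seed (LCG-style mix;
# multiplier kept small so doubles stay exact)
deriveSeed <- function(seed, ...) {
  keys <- c(...)
  s <- as.numeric(seed) %% 2147483647
  for (k in keys) s <- (s * 69069 + as.numeric(k) + 1) %% 2147483647
  as.integer(s)
}

# evaluate code under a local seed, restoring the caller's RNG state
withSeed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}
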