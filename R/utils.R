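# Seed management: every stochastic operation takes an explicit seed and
# runs in a local RNG scope so the caller's random-number stream is never
# disturbed. Stage seeds are split deterministically from a master seed so
# adding one output never perturbs another.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-stage seed derived from a master seed and a stage tag.
# Kept within 32-bit integer range.
split_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

log2p1 <- function(x) log2(x + 1)
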