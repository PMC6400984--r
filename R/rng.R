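# Seeded evaluation that leaves the caller's RNG state untouched, so every
# generator is a pure function of (arguments, seed).
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop("'seed' must be a single finite number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a distinct but reproducible child seed from a base seed; kept below
# 2^31 so it is always a valid R integer.
child_seed <- function(seed, k) {
  (as.integer(seed) * 48271 + k * 1009) %% 2147483629L
}
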