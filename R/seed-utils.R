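# RNG hygiene: every stochastic entry point takes an explicit seed and leaves
# the caller's .Random.seed untouched. Stream splits are derived from the one
# master seed so any stage is reproducible in isolation.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
  }
  force(code)
}

# deterministic substream seed, kept inside 32-bit integer range
split_seed <- function(seed, stream) {
  (as.integer(seed) * 7919L + as.integer(stream) * 104729L) %% 2147483587L
}
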