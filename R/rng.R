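# Seedable, restorable RNG plumbing.  Every stochastic component of the
# package threads an explicit RNG token (either an integer seed or a saved
# .Random.seed vector) through rng_eval(), so identical inputs give
# bit-identical outputs and the caller's RNG state is never disturbed.

.has_seed <- function() {
  exists(".Random.seed", envir = globalenv(), inherits = FALSE)
}

.get_seed <- function() get(".Random.seed", envir = globalenv(), inherits = FALSE)

.set_seed_vector <- function(s) {
  assign(".Random.seed", s, envir = globalenv())
}

# Evaluate fn() under the RNG state `rng` (integer seed or .Random.seed
# vector); returns list(value, rng) where rng is the advanced state.  The
# global RNG state is restored on exit.
rng_eval <- function(rng, fn) {
  old <- if (.has_seed()) .get_seed() else NULL
  on.exit({
    if (is.null(old)) {
      if (.has_seed()) rm(".Random.seed", envir = globalenv())
    } else {
      .set_seed_vector(old)
    }
  })
  if (length(rng) == 1L) {
    set.seed(as.integer(rng))
  } else {
    .set_seed_vector(rng)
  }
  value <- fn()
  list(value = value, rng = .get_seed())
}
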