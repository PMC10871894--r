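# RNG bookkeeping.  The reproduction stream is R's global RNG, seeded once
# per replicate.  Side processes that must not perturb it (demographic size
# draws) run on isolated substreams: a saved .Random.seed that is swapped
# in, advanced, and swapped out.

save_rng_state <- function() {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  get(".Random.seed", envir = globalenv(), inherits = FALSE)
}

restore_rng_state <- function(state) {
  assign(".Random.seed", state, envir = globalenv())
  invisible(state)
}

# Deterministic substream derived from a seed and a text label.
rng_substream <- function(seed, label) {
  old <- save_rng_state()
  on.exit(restore_rng_state(old))
  offset <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  set.seed((as.numeric(seed) + 131L * offset) %% .Machine$integer.max)
  save_rng_state()
}

# Evaluate expr with the RNG in `state`; restore the caller's stream after.
# Returns list(value, state) with the advanced substream state.
with_rng_state <- function(state, expr) {
  old <- save_rng_state()
  restore_rng_state(state)
  value <- force(expr)
  new_state <- save_rng_state()
  restore_rng_state(old)
  list(value = value, state = new_state)
}
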