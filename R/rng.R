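# Deterministic seed plumbing. The engine never disturbs the caller's RNG:
# every internal draw happens inside a saved/restored .Random.seed envelope.

#' Derive a child seed from a session seed
#'
#' Trials, spawns and simulator streams each get their own reproducible
#' RNG stream derived from the session seed and an index, so sequences
#' differ across trials but reproduce exactly across runs.
#'
#' @param seed Integer session seed.
#' @param index Non-negative integer stream index.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(index))
  # arithmetic in double: values stay far below 2^53, result below 2^31
  as.integer(((abs(seed) %% 2147483647) * 7919 + index * 104729) %% 2147483647)
}

# Run expr with the global RNG temporarily set from `state_env$state`
# (initialised from `seed` on first use); the caller's .Random.seed is
# untouched afterwards and the stream's position persists in state_env.
with_rng_stream <- function(state_env, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  if (is.null(state_env$state)) {
    set.seed(state_env$seed)
    state_env$state <- get(".Random.seed", envir = globalenv())
  }
  assign(".Random.seed", state_env$state, envir = globalenv())
  on.exit({
    state_env$state <- get(".Random.seed", envir = globalenv())
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

rng_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  e$seed <- seed
  e$state <- NULL
  e
}
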