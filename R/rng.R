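# Seedable RNG streams with explicit state, so that every source of
# randomness in a run flows from one seed, streams never touch each other,
# and the full generator state can be checkpointed and restored exactly.
# Backed by R's Mersenne-Twister; the algorithm name travels with the state.

rng_new <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  e <- new.env(parent = emptyenv())
  e$algorithm <- "Mersenne-Twister"
  e$seed <- as.integer(seed)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(e$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  e$state <- get(".Random.seed", envir = globalenv())
  restore_global_seed(old)
  e
}

restore_global_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# evaluate expr with the stream's state installed, then capture it back
with_rng <- function(rng, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", envir = globalenv())
    restore_global_seed(old)
  })
  expr
}

rng_unif <- function(rng, n = 1) with_rng(rng, stats::runif(n))

# uniforms on (0, 1]: never exactly 0, so -log(u) is finite
rng_unif_open0 <- function(rng, n = 1) 1 - rng_unif(rng, n)

rng_norm <- function(rng, n = 1) with_rng(rng, stats::rnorm(n))

# derive a fresh child seed (< 2^31) from a stream, for sub-operations
rng_spawn_seed <- function(rng) {
  as.integer(floor(rng_unif(rng, 1) * 2147483646)) + 1L
}

rng_get_state <- function(rng) {
  list(algorithm = rng$algorithm, seed = rng$seed, state = rng$state)
}

rng_set_state <- function(rng, st) {
  stopifnot(identical(st$algorithm, rng$algorithm))
  rng$state <- as.integer(st$state)
  rng$seed <- as.integer(st$seed)
  rng
}
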