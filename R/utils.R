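# Internal seeded-stream helpers: every stochastic operation seeds its own
# stream and restores the caller's RNG state, so no function consumes global
# RNG state as a side effect.

.seed_stream <- function(seed) {
  if (is.null(seed) || !is.finite(seed)) stop("a finite integer seed is required")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed %% .Machine$integer.max))
  old
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Deterministic child seed for stage k of a master seed (kept < 2^31).
.child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 16807) %% 2147483647)
}
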