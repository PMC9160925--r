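# Deterministic, worker-count-invariant random streams.
#
# Every stochastic draw in the kernel and the builders goes through a stream
# keyed by (master seed, purpose, entity id, counter). The key is hashed to a
# 31-bit seed and handed to base R's generator for the draw, so a quantity is
# reproducible no matter how many logical workers exist or in which order
# entities are visited.

.PURPOSE <- list(
  connect   = 11L,
  poisson   = 23L,
  positions = 37L,
  bias      = 47L,
  init_v    = 59L,
  generic   = 71L
)

#' Mix integer keys into a 31-bit seed
#'
#' Lehmer-style mixing of an arbitrary key sequence into `[0, 2^31 - 30)`.
#' All inputs must be non-negative numbers below 2^31 so the accumulation
#' stays exact in double precision.
#'
#' @param ... numeric key components (seed, purpose code, entity id, counter).
#' @return a single integer seed.
#' @keywords internal
mix_seed <- function(...) {
  keys <- c(...)
  stopifnot(all(is.finite(keys)), all(keys >= 0))
  m <- 2147483629 # prime < 2^31
  s <- 0
  for (x in keys) {
    s <- (s * 69069 + (x %% m) + 1) %% m
  }
  as.integer(s)
}

# Run `expr` with the stream keyed by the given ids, restoring the caller's
# RNG state afterwards so package code never disturbs user-level RNG.
with_stream <- function(seed, purpose, id, counter, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  # two-stage seeding: the Lehmer mix leaves nearby keys on an arithmetic
  # progression, so one generator draw is used as an avalanche round before
  # the stream is seeded for real
  set.seed(mix_seed(seed, .PURPOSE[[purpose]], id, counter))
  set.seed(sample.int(2147483646L, 1L))
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  expr
}
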