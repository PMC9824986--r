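# Internal utilities: seeded RNG streams and a config hash.
#
# All randomness in the package flows through `new_rng()` streams so that a
# single root seed determines every draw, independent of the caller's
# global RNG state.

new_rng <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  e <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  e$state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  else rm(".Random.seed", envir = globalenv())
  class(e) <- "rng_stream"
  e
}

# evaluate fun() with the stream's RNG state swapped in, persisting it after
rng_eval <- function(rng, fun) {
  stopifnot(inherits(rng, "rng_stream"))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", rng$state, globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  fun()
}

# derive an independent child stream (kept below 2^31)
split_rng <- function(rng, index) {
  child_seed <- rng_eval(rng, function()
    sample.int(.Machine$integer.max - 1L, 1L))
  new_rng((child_seed + index) %% (.Machine$integer.max - 1L))
}

sample_int <- function(rng, n, size, replace = FALSE, prob = NULL)
  rng_eval(rng, function() sample.int(n, size, replace = replace, prob = prob))

runif_rng <- function(rng, n, min = 0, max = 1)
  rng_eval(rng, function() stats::runif(n, min, max))

rnorm_rng <- function(rng, n, mean = 0, sd = 1)
  rng_eval(rng, function() stats::rnorm(n, mean, sd))

rbinom_rng <- function(rng, n, prob)
  rng_eval(rng, function() stats::rbinom(n, 1L, prob))

`%||%` <- function(a, b) if (is.null(a)) b else a

# FNV-1a over the serialized object; stable fingerprint for manifests
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

# truncated-normal draw via inverse-cdf (vectorised)
rtruncnorm_rng <- function(rng, n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- runif_rng(rng, n)
  stats::qnorm(plo + u * (phi - plo), mean, sd)
}
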