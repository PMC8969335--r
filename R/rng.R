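# Seed-isolated RNG streams. Each stream owns a private .Random.seed state so
# tree construction, generators and harnesses are reproducible without
# touching (or depending on) the caller's global RNG.

make_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, globalenv())
  }
  env
}

with_rng <- function(rng, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  assign(".Random.seed", rng$state, globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv())
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, globalenv())
    }
  })
  expr
}

# sample elements of x; never expands a scalar x into 1:x
rng_sample <- function(rng, x, size = length(x), replace = FALSE) {
  with_rng(rng, x[sample.int(length(x), size, replace = replace)])
}

# sample indices from 1..n
rng_sample_int <- function(rng, n, size = n, replace = FALSE) {
  with_rng(rng, sample.int(n, size, replace = replace))
}

rng_runif <- function(rng, n, min = 0, max = 1) {
  with_rng(rng, stats::runif(n, min, max))
}

rng_rbinom <- function(rng, n, size, prob) {
  with_rng(rng, stats::rbinom(n, size, prob))
}

rng_rnorm <- function(rng, n, mean = 0, sd = 1) {
  with_rng(rng, stats::rnorm(n, mean, sd))
}

rng_rbeta <- function(rng, n, shape1, shape2) {
  with_rng(rng, stats::rbeta(n, shape1, shape2))
}

# child seed for an independent sub-stream (kept within 32-bit range)
rng_child_seed <- function(rng) {
  with_rng(rng, sample.int(.Machine$integer.max - 1L, 1L))
}
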