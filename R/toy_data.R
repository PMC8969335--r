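# Small 2-D toy generators used to probe decision-boundary shape: linearly
# inseparable two-spiral and concentric-ring problems, the two-moons
# problem, and separable Gaussian blobs.

#' Two interleaved spirals
#'
#' The classic benchmark construction: points evenly spaced in angle along
#' an Archimedean arm starting at a quarter turn (so the arms never meet at
#' the origin), the second arm the point reflection of the first, plus
#' isotropic Gaussian noise. Even angular spacing keeps the two classes
#' point-symmetric, so linear classifiers sit at chance while the decision
#' boundary stays smoothly curved.
#'
#' @param n samples per class.
#' @param noise Gaussian noise sd added to both coordinates.
#' @param turns number of spiral revolutions.
#' @param seed integer seed or RNG stream.
#' @return list with `x` (n*2 x 2 matrix) and `y` (class labels "A"/"B").
#' @export
make_two_spirals <- function(n = 100L, noise = 0.05, turns = 2, seed = 1L) {
  rng <- if (is.environment(seed)) seed else make_rng(seed)
  theta_max <- pi / 2 + 2 * pi * turns
  theta <- seq(pi / 2, theta_max, length.out = n)
  r <- theta / theta_max
  x1 <- cbind(r * cos(theta), r * sin(theta))
  x <- rbind(x1, -x1) + matrix(rng_rnorm(rng, 4 * n, sd = noise), 2 * n, 2)
  list(x = x, y = rep(c("A", "B"), each = n))
}

#' Concentric circles
#'
#' @param n samples per class.
#' @param noise Gaussian noise sd.
#' @param scale radius of the inner circle relative to the outer.
#' @param seed integer seed or RNG stream.
#' @return list with `x` and `y`.
#' @export
make_circles <- function(n = 100L, noise = 0.08, scale = 0.5, seed = 1L) {
  rng <- if (is.environment(seed)) seed else make_rng(seed)
  t1 <- rng_runif(rng, n, 0, 2 * pi)
  t2 <- rng_runif(rng, n, 0, 2 * pi)
  x <- rbind(cbind(cos(t1), sin(t1)),
             scale * cbind(cos(t2), sin(t2)))
  x <- x + matrix(rng_rnorm(rng, 4 * n, sd = noise), 2 * n, 2)
  list(x = x, y = rep(c("A", "B"), each = n))
}

#' Two moons
#'
#' @param n samples per class.
#' @param noise Gaussian noise sd.
#' @param seed integer seed or RNG stream.
#' @return list with `x` and `y`.
#' @export
make_moons <- function(n = 100L, noise = 0.1, seed = 1L) {
  rng <- if (is.environment(seed)) seed else make_rng(seed)
  t1 <- rng_runif(rng, n, 0, pi)
  t2 <- rng_runif(rng, n, 0, pi)
  x <- rbind(cbind(cos(t1), sin(t1)),
             cbind(1 - cos(t2), 0.5 - sin(t2)))
  x <- x + matrix(rng_rnorm(rng, 4 * n, sd = noise), 2 * n, 2)
  list(x = x, y = rep(c("A", "B"), each = n))
}

#' Separable Gaussian blobs
#'
#' @param n samples per class.
#' @param centers matrix of class centers (rows).
#' @param sd within-class standard deviation.
#' @param seed integer seed or RNG stream.
#' @return list with `x` and `y`.
#' @export
make_blobs <- function(n = 50L, centers = rbind(c(-2, 0), c(2, 0)),
                       sd = 0.5, seed = 1L) {
  rng <- if (is.environment(seed)) seed else make_rng(seed)
  k <- nrow(centers)
  x <- do.call(rbind, lapply(seq_len(k), function(i) {
    sweep(matrix(rng_rnorm(rng, n * ncol(centers), sd = sd), n), 2,
          centers[i, ], `+`)
  }))
  list(x = x, y = rep(LETTERS[seq_len(k)], each = n))
}
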