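# Stochastic-gradient linear classifiers (hinge, modified-Huber or squared-
# hinge loss; L2 or elastic-net penalty). No installed R package exposes this
# family directly, so it is implemented here: shuffled mini-batch subgradient
# descent with an inverse-scaling learning rate, one-vs-rest for more than
# two classes.

sgd_loss_grad <- function(loss, z) {
  # derivative of the margin loss L(z) wrt the score f (z = y * f), as the
  # factor multiplying -y
  switch(loss,
    hinge = (z < 1) + 0,
    squared_hinge = 2 * pmax(1 - z, 0),
    modified_huber = pmin(pmax(2 * (1 - z), 0), 4),
    stop("unknown SGD loss: ", loss)
  )
}

# fit a whole grid of (loss, alpha) cells simultaneously: weights are kept
# as a d x n_cells matrix so every mini-batch update is a single BLAS call
sgd_fit_grid <- function(X, y01, loss_vec, alpha_vec, penalty,
                         l1_ratio = 0.15, epochs = 15L, batch_size = 32L,
                         rng = NULL) {
  n <- nrow(X)
  d <- ncol(X)
  m <- length(alpha_vec)
  stopifnot(length(loss_vec) == m)
  W <- matrix(0, d, m)
  b <- numeric(m)
  ysgn <- y01 * 2 - 1
  t <- 0
  loss_groups <- split(seq_len(m), loss_vec)
  starts <- seq(1L, n, by = batch_size)
  for (ep in seq_len(epochs)) {
    idx <- rng_sample_int(rng, n)
    for (s in starts) {
      batch <- idx[s:min(s + batch_size - 1L, n)]
      nb <- length(batch)
      Xb <- X[batch, , drop = FALSE]
      yb <- ysgn[batch]
      Z <- yb * (Xb %*% W + rep(b, each = nb))
      G <- Z
      for (lt in names(loss_groups)) {
        cols <- loss_groups[[lt]]
        G[, cols] <- sgd_loss_grad(lt, Z[, cols, drop = FALSE])
      }
      eta <- 1 / (10 + alpha_vec * t)
      YG <- yb * G
      stepW <- crossprod(Xb, YG) / nb
      reg <- if (penalty == "elasticnet") {
        l1_ratio * sign(W) + (1 - l1_ratio) * W
      } else {
        W
      }
      ew <- rep(eta, each = d)
      W <- W + stepW * ew - reg * (ew * rep(alpha_vec, each = d))
      b <- b + eta * (colSums(YG) / nb)
      t <- t + 1
    }
  }
  list(W = W, b = b)
}

sgd_fit_binary <- function(X, y01, loss, alpha, penalty, l1_ratio, epochs,
                           batch_size, tol, rng) {
  n <- nrow(X)
  d <- ncol(X)
  w <- numeric(d)
  b <- 0
  ysgn <- y01 * 2 - 1
  t <- 0
  best <- Inf
  stall <- 0L
  for (ep in seq_len(epochs)) {
    idx <- rng_sample_int(rng, n)
    starts <- seq(1L, n, by = batch_size)
    for (s in starts) {
      batch <- idx[s:min(s + batch_size - 1L, n)]
      Xb <- X[batch, , drop = FALSE]
      yb <- ysgn[batch]
      f <- drop(Xb %*% w) + b
      g <- sgd_loss_grad(loss, yb * f)
      eta <- 1 / (10 + alpha * t)
      grad_w <- -crossprod(Xb, yb * g) / length(batch)
      grad_b <- -mean(yb * g)
      reg <- if (penalty == "elasticnet") {
        alpha * (l1_ratio * sign(w) + (1 - l1_ratio) * w)
      } else {
        alpha * w
      }
      w <- w - eta * (drop(grad_w) + reg)
      b <- b - eta * grad_b
      t <- t + 1
    }
    f <- drop(X %*% w) + b
    z <- ysgn * f
    obj <- mean(switch(loss,
      hinge = pmax(1 - z, 0),
      squared_hinge = pmax(1 - z, 0)^2,
      modified_huber = ifelse(z >= 1, 0, ifelse(z >= -1, (1 - z)^2, -4 * z))
    ))
    if (obj > best - tol) stall <- stall + 1L else stall <- 0L
    if (obj < best) best <- obj
    if (stall >= 5L) break
  }
  list(w = w, b = b)
}

# grid-of-cells prediction used by cross-validated grid searches; one-vs-rest
# above two classes
sgd_grid_predict <- function(Xtr, ytr, Xte, loss_vec, alpha_vec, penalty,
                             epochs = 15L, rng = NULL) {
  labels <- sort(unique(ytr))
  m <- length(alpha_vec)
  if (length(labels) == 2L) {
    f <- sgd_fit_grid(Xtr, as.numeric(ytr == labels[2]), loss_vec, alpha_vec,
                      penalty, epochs = epochs, rng = rng)
    S <- sweep(Xte %*% f$W, 2, f$b, `+`)
    matrix(labels[1L + (S >= 0)], nrow(Xte), m)
  } else {
    A <- array(0, c(nrow(Xte), m, length(labels)))
    for (k in seq_along(labels)) {
      f <- sgd_fit_grid(Xtr, as.numeric(ytr == labels[k]), loss_vec,
                        alpha_vec, penalty, epochs = epochs, rng = rng)
      A[, , k] <- sweep(Xte %*% f$W, 2, f$b, `+`)
    }
    out <- matrix("", nrow(Xte), m)
    for (j in seq_len(m)) {
      S <- matrix(A[, j, ], ncol = length(labels))
      out[, j] <- labels[max.col(S, ties.method = "first")]
    }
    out
  }
}

sgd_classifier <- function(X, y, loss = "hinge", alpha = 1e-3,
                           penalty = "l2", l1_ratio = 0.15, epochs = 60L,
                           batch_size = 16L, tol = 1e-4, seed = 1L) {
  rng <- if (is.environment(seed)) seed else make_rng(seed)
  y <- as.character(y)
  labels <- sort(unique(y))
  batch_size <- min(batch_size, nrow(X))
  if (length(labels) == 2L) {
    f <- sgd_fit_binary(X, as.numeric(y == labels[2]), loss, alpha, penalty,
                        l1_ratio, epochs, batch_size, tol, rng)
    W <- matrix(f$w, ncol = 1)
    b <- f$b
  } else {
    W <- matrix(0, ncol(X), length(labels))
    b <- numeric(length(labels))
    for (k in seq_along(labels)) {
      f <- sgd_fit_binary(X, as.numeric(y == labels[k]), loss, alpha,
                          penalty, l1_ratio, epochs, batch_size, tol, rng)
      W[, k] <- f$w
      b[k] <- f$b
    }
  }
  list(W = W, b = b, labels = labels, loss = loss, alpha = alpha,
       penalty = penalty)
}

sgd_predict <- function(model, X) {
  S <- X %*% model$W
  S <- sweep(S, 2, model$b, `+`)
  if (ncol(S) == 1L) {
    model$labels[1L + (drop(S) >= 0)]
  } else {
    model$labels[max.col(S, ties.method = "first")]
  }
}
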