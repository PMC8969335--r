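# Two-branch neural network splitter, implemented directly in R numerics.
#
# Branch A: dense layers of 256, 128, 64, 48 and 24 units with mish
# activations and alpha dropout (rate 0.2) after the first three layers.
# Branch B: a fixed random-Fourier-features projection of the input to 24
# dimensions (unit-Gaussian kernel bandwidth) followed by dense layers of
# 24, 24 and 16 units. The branch outputs are concatenated and fed to a
# softmax layer over the node's classes. Training minimizes categorical
# cross-entropy with Adam (learning rate 0.001), batch size 32, a 90/10
# train/validation split and at most 300 epochs with early stopping
# (min_delta 1e-4, patience 40). Offered only at nodes with more than 32
# samples.

mish <- function(x) {
  sp <- ifelse(x > 20, x, log1p(exp(pmin(x, 20))))
  x * tanh(sp)
}

mish_grad <- function(x) {
  sp <- ifelse(x > 20, x, log1p(exp(pmin(x, 20))))
  t <- tanh(sp)
  sig <- 1 / (1 + exp(-pmax(pmin(x, 30), -30)))
  t + x * (1 - t^2) * sig
}

ALPHA_DROP_ALPHA <- -1.7580993408473766

alpha_dropout_mask <- function(dim, p, rng) {
  matrix(rng_runif(rng, prod(dim)) >= p, dim[1], dim[2])
}

apply_alpha_dropout <- function(h, mask, p) {
  a <- ((1 - p) * (1 + p * ALPHA_DROP_ALPHA^2))^(-0.5)
  b <- -a * p * ALPHA_DROP_ALPHA
  list(out = a * (h * mask + ALPHA_DROP_ALPHA * (1 - mask)) + b,
       grad_factor = a * mask)
}

nnet_init_layer <- function(n_in, n_out, rng) {
  list(W = matrix(rng_rnorm(rng, n_in * n_out, sd = sqrt(2 / n_in)),
                  n_in, n_out),
       b = numeric(n_out))
}

adam_state <- function(layers) {
  lapply(layers, function(l) list(mW = l$W * 0, vW = l$W * 0,
                                  mb = l$b * 0, vb = l$b * 0))
}

adam_update <- function(layer, st, gW, gb, lr, t, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  st$mW <- beta1 * st$mW + (1 - beta1) * gW
  st$vW <- beta2 * st$vW + (1 - beta2) * gW^2
  st$mb <- beta1 * st$mb + (1 - beta1) * gb
  st$vb <- beta2 * st$vb + (1 - beta2) * gb^2
  mhW <- st$mW / (1 - beta1^t); vhW <- st$vW / (1 - beta2^t)
  mhb <- st$mb / (1 - beta1^t); vhb <- st$vb / (1 - beta2^t)
  layer$W <- layer$W - lr * mhW / (sqrt(vhW) + eps)
  layer$b <- layer$b - lr * mhb / (sqrt(vhb) + eps)
  list(layer = layer, state = st)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# forward pass through one branch; returns caches for backprop
branch_forward <- function(X, layers, drop_after, p, rng, training) {
  h <- X
  caches <- vector("list", length(layers))
  for (l in seq_along(layers)) {
    a <- sweep(h %*% layers[[l]]$W, 2, layers[[l]]$b, `+`)
    act <- mish(a)
    cache <- list(input = h, pre = a, drop = NULL)
    if (training && l %in% drop_after) {
      mask <- alpha_dropout_mask(dim(act), p, rng)
      ad <- apply_alpha_dropout(act, mask, p)
      act <- ad$out
      cache$drop <- ad$grad_factor
    }
    caches[[l]] <- cache
    h <- act
  }
  list(out = h, caches = caches)
}

branch_backward <- function(delta, layers, caches) {
  grads <- vector("list", length(layers))
  for (l in rev(seq_along(layers))) {
    cc <- caches[[l]]
    if (!is.null(cc$drop)) delta <- delta * cc$drop
    delta <- delta * mish_grad(cc$pre)
    grads[[l]] <- list(gW = crossprod(cc$input, delta),
                       gb = colSums(delta))
    delta <- delta %*% t(layers[[l]]$W)
  }
  list(grads = grads, delta_input = delta)
}

#' Fit the two-branch neural network splitter
#'
#' @param X node sample matrix.
#' @param y node labels (>= 2 classes); the node must have more than 32
#'   samples.
#' @param rng RNG stream or integer seed.
#' @param feature_subset optional column indices the network reads.
#' @param epochs,batch_size,lr,patience,min_delta,val_split,dropout training
#'   controls; defaults follow the standard configuration (300 epochs, batch
#'   32, Adam at 0.001, patience 40, min_delta 1e-4, 10% validation, alpha
#'   dropout 0.2).
#' @return a fitted splitter of kind `"nnet"`.
#' @export
fit_neural_splitter <- function(X, y, rng = 1L, feature_subset = NULL,
                                epochs = 300L, batch_size = 32L, lr = 0.001,
                                patience = 40L, min_delta = 1e-4,
                                val_split = 0.1, dropout = 0.2) {
  if (!is.environment(rng)) rng <- make_rng(rng)
  y <- as.character(y)
  if (nrow(X) <= 32L) stop("neural splitter requires more than 32 samples")
  labels <- sort(unique(y))
  if (length(labels) < 2L) stop("single-class node cannot be split")
  idx <- if (is.null(feature_subset)) seq_len(ncol(X)) else sort(feature_subset)
  Xs <- X[, idx, drop = FALSE]
  d <- ncol(Xs)
  k <- length(labels)
  Y <- stats::model.matrix(~ factor(y, levels = labels) - 1)

  widths_a <- c(256L, 128L, 64L, 48L, 24L)
  widths_b <- c(24L, 24L, 16L)
  rff_dim <- 24L
  Omega <- matrix(rng_rnorm(rng, d * rff_dim), d, rff_dim)
  beta <- rng_runif(rng, rff_dim, 0, 2 * pi)

  layers_a <- list()
  n_in <- d
  for (w in widths_a) {
    layers_a[[length(layers_a) + 1L]] <- nnet_init_layer(n_in, w, rng)
    n_in <- w
  }
  layers_b <- list()
  n_in <- rff_dim
  for (w in widths_b) {
    layers_b[[length(layers_b) + 1L]] <- nnet_init_layer(n_in, w, rng)
    n_in <- w
  }
  out_layer <- nnet_init_layer(tail(widths_a, 1) + tail(widths_b, 1), k, rng)

  n <- nrow(Xs)
  n_val <- max(1L, floor(val_split * n))
  val_idx <- rng_sample_int(rng, n, n_val)
  tr_idx <- setdiff(seq_len(n), val_idx)
  rff <- function(M) sqrt(2 / rff_dim) * cos(sweep(M %*% Omega, 2, beta, `+`))
  Xtr <- Xs[tr_idx, , drop = FALSE]; Ytr <- Y[tr_idx, , drop = FALSE]
  Xval <- Xs[val_idx, , drop = FALSE]; Yval <- Y[val_idx, , drop = FALSE]
  Rtr <- rff(Xtr); Rval <- rff(Xval)

  st_a <- adam_state(layers_a)
  st_b <- adam_state(layers_b)
  st_o <- adam_state(list(out_layer))[[1]]
  t_step <- 0
  best_val <- Inf
  stall <- 0L
  for (ep in seq_len(epochs)) {
    ord <- rng_sample_int(rng, length(tr_idx))
    for (s in seq(1L, length(tr_idx), by = batch_size)) {
      batch <- ord[s:min(s + batch_size - 1L, length(tr_idx))]
      Xb <- Xtr[batch, , drop = FALSE]
      Rb <- Rtr[batch, , drop = FALSE]
      Yb <- Ytr[batch, , drop = FALSE]
      fa <- branch_forward(Xb, layers_a, drop_after = 1:3, p = dropout,
                           rng = rng, training = TRUE)
      fb <- branch_forward(Rb, layers_b, drop_after = integer(0), p = dropout,
                           rng = rng, training = FALSE)
      H <- cbind(fa$out, fb$out)
      Z <- sweep(H %*% out_layer$W, 2, out_layer$b, `+`)
      P <- softmax_rows(Z)
      dZ <- (P - Yb) / nrow(Xb)
      gWo <- crossprod(H, dZ)
      gbo <- colSums(dZ)
      dH <- dZ %*% t(out_layer$W)
      na <- ncol(fa$out)
      ba <- branch_backward(dH[, seq_len(na), drop = FALSE], layers_a, fa$caches)
      bb <- branch_backward(dH[, -seq_len(na), drop = FALSE], layers_b, fb$caches)
      t_step <- t_step + 1
      up <- adam_update(out_layer, st_o, gWo, gbo, lr, t_step)
      out_layer <- up$layer; st_o <- up$state
      for (l in seq_along(layers_a)) {
        up <- adam_update(layers_a[[l]], st_a[[l]], ba$grads[[l]]$gW,
                          ba$grads[[l]]$gb, lr, t_step)
        layers_a[[l]] <- up$layer; st_a[[l]] <- up$state
      }
      for (l in seq_along(layers_b)) {
        up <- adam_update(layers_b[[l]], st_b[[l]], bb$grads[[l]]$gW,
                          bb$grads[[l]]$gb, lr, t_step)
        layers_b[[l]] <- up$layer; st_b[[l]] <- up$state
      }
    }
    # validation loss for early stopping
    fa <- branch_forward(Xval, layers_a, integer(0), dropout, rng, FALSE)
    fb <- branch_forward(Rval, layers_b, integer(0), dropout, rng, FALSE)
    P <- softmax_rows(sweep(cbind(fa$out, fb$out) %*% out_layer$W, 2,
                            out_layer$b, `+`))
    val_loss <- -mean(rowSums(Yval * log(pmax(P, 1e-12))))
    if (val_loss < best_val - min_delta) {
      best_val <- val_loss
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    if (stall >= patience) break
  }
  structure(
    list(family = "neural_net", kind = "nnet", layers_a = layers_a,
         layers_b = layers_b, out_layer = out_layer, Omega = Omega,
         beta = beta, rff_dim = rff_dim, branch_labels = labels,
         feature_idx = idx, params = list(epochs = epochs, lr = lr),
         achieved_gain = NA_real_),
    class = "landmark_splitter"
  )
}

nnet_forward_probs <- function(splitter, X) {
  Xs <- X[, splitter$feature_idx, drop = FALSE]
  R <- sqrt(2 / splitter$rff_dim) *
    cos(sweep(Xs %*% splitter$Omega, 2, splitter$beta, `+`))
  fa <- branch_forward(Xs, splitter$layers_a, integer(0), 0, NULL, FALSE)
  fb <- branch_forward(R, splitter$layers_b, integer(0), 0, NULL, FALSE)
  softmax_rows(sweep(cbind(fa$out, fb$out) %*% splitter$out_layer$W, 2,
                     splitter$out_layer$b, `+`))
}

nnet_predict <- function(splitter, X) {
  P <- nnet_forward_probs(splitter, X)
  splitter$branch_labels[max.col(P, ties.method = "first")]
}
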