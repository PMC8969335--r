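# Kernel-weighted Shapley value estimation (model-agnostic). Absent
# features are imputed from a background set; coalition values are solved
# by the kernel-weighted linear regression with the efficiency constraint
# eliminated analytically, so local accuracy (attributions plus base value
# reproduce the model output) holds exactly in enumeration mode.

shap_kernel_weight <- function(d, s) {
  (d - 1) / (choose(d, s) * s * (d - s))
}

# value of coalition set S for sample x: average model output with the
# features outside S replaced by each background row in turn
coalition_inputs <- function(x, background, Z) {
  n_b <- nrow(background)
  n_z <- nrow(Z)
  d <- length(x)
  out <- background[rep(seq_len(n_b), times = n_z), , drop = FALSE]
  xrep <- matrix(x, n_z * n_b, d, byrow = TRUE)
  mask <- Z[rep(seq_len(n_z), each = n_b), , drop = FALSE] == 1
  out[mask] <- xrep[mask]
  out
}

kernel_shap_one <- function(f, x, background, n_coalition_samples,
                            exact_limit, rng) {
  d <- length(x)
  f0 <- mean(f(background))
  fx <- f(matrix(x, 1))
  if (d == 1L) return(list(phi = fx - f0, base = f0))
  if (d <= exact_limit) {
    sizes <- 1:(d - 1)
    Z <- do.call(rbind, lapply(sizes, function(s) {
      t(apply(utils::combn(d, s), 2, function(ix) {
        z <- numeric(d); z[ix] <- 1; z
      }))
    }))
    w <- apply(Z, 1, function(z) shap_kernel_weight(d, sum(z)))
  } else {
    probs <- vapply(1:(d - 1), function(s) shap_kernel_weight(d, s) * choose(d, s), 0)
    probs <- probs / sum(probs)
    # draw coalition sizes from the kernel distribution, then a uniform
    # subset of that size
    u <- rng_runif(rng, n_coalition_samples)
    sizes <- findInterval(u, cumsum(probs)) + 1L
    Z <- t(vapply(sizes, function(s) {
      z <- numeric(d); z[rng_sample_int(rng, d, s)] <- 1; z
    }, numeric(d)))
    w <- rep(1, nrow(Z))  # kernel absorbed by the sampling distribution
  }
  v <- colMeans(matrix(f(coalition_inputs(x, background, Z)),
                       nrow = nrow(background)))
  # eliminate phi_d via the efficiency constraint sum(phi) = fx - f0
  Zt <- Z[, -d, drop = FALSE] - Z[, d]
  yt <- v - f0 - Z[, d] * (fx - f0)
  A <- crossprod(Zt * w, Zt)
  b <- crossprod(Zt * w, yt)
  phi_head <- tryCatch(drop(solve(A + diag(1e-10, ncol(A)), b)),
                       error = function(e) rep(0, ncol(A)))
  phi <- c(phi_head, (fx - f0) - sum(phi_head))
  list(phi = phi, base = f0)
}

#' Kernel Shapley attributions for one or more samples
#'
#' For up to `exact_limit` features every coalition is enumerated and the
#' attributions are exact (local accuracy to numerical precision);
#' otherwise `n_coalition_samples` coalitions are drawn from the Shapley
#' kernel distribution.
#'
#' @param f prediction function: matrix in, numeric vector out (e.g. a
#'   class probability).
#' @param X_explain samples to explain (matrix, rows = samples).
#' @param background background samples used to impute absent features.
#' @param n_coalition_samples coalition budget per explained sample in
#'   sampling mode (default 768).
#' @param exact_limit maximum feature count for exhaustive enumeration.
#' @param seed integer seed or RNG stream.
#' @return list with `phi` (samples x features attribution matrix) and
#'   `base_value`.
#' @export
kernel_shap <- function(f, X_explain, background,
                        n_coalition_samples = 768L, exact_limit = 13L,
                        seed = 1L) {
  rng <- if (is.environment(seed)) seed else make_rng(seed)
  X_explain <- as.matrix(X_explain)
  background <- as.matrix(background)
  if (nrow(background) == 0L) stop("background set must be non-empty")
  phi <- matrix(0, nrow(X_explain), ncol(X_explain),
                dimnames = list(rownames(X_explain), colnames(X_explain)))
  base <- NA_real_
  for (i in seq_len(nrow(X_explain))) {
    res <- kernel_shap_one(f, X_explain[i, ], background,
                           n_coalition_samples, exact_limit, rng)
    phi[i, ] <- res$phi
    base <- res$base
  }
  list(phi = phi, base_value = base)
}

#' Mean-absolute Shapley feature importance
#'
#' Estimates per-sample Shapley attributions with [kernel_shap()] and
#' summarizes each feature by the mean absolute attribution across the
#' explained samples -- the importance proxy used for splitter ensembles,
#' whose per-feature effects have no closed form.
#'
#' @param model a fitted `landmark_ensemble`, or a prediction function
#'   (matrix in, numeric vector out).
#' @param X_explain samples to explain.
#' @param background background samples (defaults to `X_explain`).
#' @param class_of_interest for ensemble models, the class whose
#'   probability is explained (default: last class in declared order).
#' @inheritParams kernel_shap
#' @return named non-negative importance vector (class
#'   `importance_vector`, provenance `"shapley_mean_abs"`).
#' @export
shapley_importance <- function(model, X_explain, background = X_explain,
                               n_coalition_samples = 768L,
                               class_of_interest = NULL, exact_limit = 13L,
                               seed = 1L) {
  f <- if (is.function(model)) {
    model
  } else if (inherits(model, "landmark_ensemble")) {
    cls <- class_of_interest %||% model$classes[length(model$classes)]
    function(M) predict(model, M, type = "prob")[, cls]
  } else {
    stop("model must be a prediction function or a landmark_ensemble")
  }
  res <- kernel_shap(f, X_explain, background, n_coalition_samples,
                     exact_limit, seed)
  out <- colMeans(abs(res$phi))
  if (stats::sd(f(as.matrix(X_explain))) == 0) out[] <- 0
  attr(out, "provenance") <- "shapley_mean_abs"
  class(out) <- c("importance_vector", class(out))
  out
}
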