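# Candidate splitter models fitted at each tree node.
#
# Six linear configurations (L2/L1 logistic regression, linear SVC, two
# stochastic-gradient linear models, ridge classification) plus a two-branch
# neural network (neural_net.R). Every fitted splitter is reduced to plain
# numeric weights so prediction, serialization and importance extraction are
# uniform across backends.

LINEAR_FAMILIES <- c("logistic_l2", "logistic_l1", "linear_svc",
                     "sgd_l2", "sgd_elasticnet", "ridge")

# Table-driven configuration: which families read a random feature subset
# ("Full" families always see every node feature), and the minimum node sizes
# at which a family is offered / tuned.
splitter_family_info <- function(family) {
  switch(family,
    logistic_l2    = list(subset = TRUE,  min_fit = 2L),
    logistic_l1    = list(subset = FALSE, min_fit = 2L),
    linear_svc     = list(subset = TRUE,  min_fit = 2L),
    sgd_l2         = list(subset = TRUE,  min_fit = 2L),
    sgd_elasticnet = list(subset = FALSE, min_fit = 2L),
    ridge          = list(subset = TRUE,  min_fit = 7L),
    neural_net     = list(subset = TRUE,  min_fit = 33L),
    stop("unknown splitter family: ", family)
  )
}

#' Hyperparameter grids for node splitters
#'
#' Regularization grids used by the per-node grid search: 20 logarithmically
#' spaced values of `C` in `[1e-4, 1e4]` for the logistic families, the set
#' `{0.001, 0.01, 0.1, 1, 10, 100}` for the SVC `C` and the SGD `alpha`
#' (crossed with the hinge and modified-Huber losses), and 20 logarithmically
#' spaced ridge penalties in `[1e-3, 1e4]` scored by generalized
#' cross-validation.
#'
#' @return named list of grids.
#' @export
splitter_grids <- function() {
  list(
    logistic_C = 10^seq(-4, 4, length.out = 20),
    svc_C      = c(0.001, 0.01, 0.1, 1, 10, 100),
    sgd_alpha  = c(0.001, 0.01, 0.1, 1, 10, 100),
    sgd_loss   = c("hinge", "modified_huber"),
    ridge_alpha = 10^seq(-3, 4, length.out = 20)
  )
}

# stratified fold assignment (1..k per sample); shuffles within class
stratified_folds <- function(y, k, rng) {
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- rng_sample(rng, idx, length(idx))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# mean CV score (balanced accuracy, verbatim confusion-matrix form) of each
# grid cell; fit_predict(X_tr, y_tr, X_te, cell) -> predicted labels for all
# cells at once (matrix n_te x n_cells) or one cell (vector)
cv_grid_scores <- function(X, y, n_cells, fit_predict, k, rng) {
  folds <- stratified_folds(y, k, rng)
  scores <- matrix(NA_real_, k, n_cells)
  classes <- sort(unique(y))
  for (f in seq_len(k)) {
    te <- folds == f
    if (!any(te) || length(unique(y[!te])) < 2L) next
    preds <- fit_predict(X[!te, , drop = FALSE], y[!te], X[te, , drop = FALSE])
    preds <- as.matrix(preds)
    # balanced accuracy (max-marginal form) for all grid cells at once
    per_class <- matrix(0, length(classes), n_cells)
    active <- matrix(FALSE, length(classes), n_cells)
    yt <- y[te]
    for (ci in seq_along(classes)) {
      is_c <- preds == classes[ci]
      col_tot <- colSums(is_c)
      diag_c <- colSums(is_c & (yt == classes[ci]))
      row_tot <- sum(yt == classes[ci])
      mx <- pmax(row_tot, col_tot)
      act <- mx > 0
      per_class[ci, act] <- diag_c[act] / mx[act]
      active[ci, ] <- act
    }
    scores[f, ] <- colSums(per_class) / pmax(colSums(active), 1L)
  }
  colMeans(scores, na.rm = TRUE)
}

#' Select per-node hyperparameters by stratified cross-validated grid search
#'
#' Applied only at nodes with more than 6 samples; smaller nodes use the
#' fixed defaults (`C = 1`, `alpha = 1`, SGD loss drawn uniformly at random).
#' The fold count is reduced below 5 when the smallest class cannot populate
#' five folds, down to 2; below that the defaults are returned. Ties are
#' broken in favour of the first grid value. Ridge uses generalized
#' cross-validation instead (see [fit_linear_splitter()]).
#'
#' @param family one of the linear splitter families.
#' @param X numeric matrix of node samples (rows) by features.
#' @param y class label per node sample.
#' @param rng internal RNG stream (or an integer seed).
#' @return list with elements among `C`, `alpha`, `loss`.
#' @export
select_hyperparameters <- function(family, X, y, rng = 1L) {
  if (!is.environment(rng)) rng <- make_rng(rng)
  y <- as.character(y)
  g <- splitter_grids()
  defaults <- switch(family,
    logistic_l2 = , logistic_l1 = , linear_svc = list(C = 1.0),
    sgd_l2 = , sgd_elasticnet =
      list(alpha = 1.0, loss = rng_sample(rng, g$sgd_loss, 1L)),
    ridge = list(alpha = 1.0),
    stop("no grid search defined for family: ", family)
  )
  n <- nrow(X)
  k <- min(5L, min(table(y)))
  if (n <= 6L || k < 2L) return(defaults)
  if (family %in% c("logistic_l2", "logistic_l1")) {
    Cs <- g$logistic_C
    alpha <- if (family == "logistic_l1") 1 else 0
    lambdas <- 1 / (Cs * n)
    labels <- sort(unique(y))
    if (family == "logistic_l2" && length(labels) == 2L &&
        ncol(X) <= RIDGE_LOGISTIC_IRLS_MAX_D) {
      fit_predict <- function(Xtr, ytr, Xte) {
        B <- ridge_logistic_path(Xtr, as.numeric(ytr == labels[2]), lambdas)
        S <- cbind(1, Xte) %*% B
        matrix(labels[1L + (S > 0)], nrow(Xte), length(Cs))
      }
      sc <- cv_grid_scores(X, y, length(Cs), fit_predict, k, rng)
      return(list(C = Cs[which.max(sc)]))
    }
    ord <- order(lambdas, decreasing = TRUE)
    fit_predict <- function(Xtr, ytr, Xte) {
      fit <- tryCatch(
        glmnet_fit(Xtr, ytr, alpha = alpha, lambda = lambdas[ord]),
        error = function(e) NULL)
      if (is.null(fit)) {
        return(matrix(names(which.max(table(ytr))), nrow(Xte), length(Cs)))
      }
      p <- glmnet_predict_class(fit, Xte, lambdas)
      p
    }
    sc <- cv_grid_scores(X, y, length(Cs), fit_predict, k, rng)
    return(list(C = Cs[which.max(sc)]))
  }
  if (family == "linear_svc") {
    Cs <- g$svc_C
    # CV probes only rank the grid; a looser KKT tolerance keeps libsvm
    # from burning time on hard-to-separate folds at large cost values
    fit_predict <- function(Xtr, ytr, Xte) {
      sapply(Cs, function(C) {
        m <- tryCatch(
          e1071::svm(Xtr, factor(ytr), kernel = "linear", cost = C,
                     scale = FALSE, type = "C-classification",
                     tolerance = 0.01),
          error = function(e) NULL)
        if (is.null(m)) rep(names(which.max(table(ytr))), nrow(Xte))
        else as.character(stats::predict(m, Xte))
      })
    }
    sc <- cv_grid_scores(X, y, length(Cs), fit_predict, k, rng)
    return(list(C = Cs[which.max(sc)]))
  }
  if (family %in% c("sgd_l2", "sgd_elasticnet")) {
    grid <- expand.grid(loss = g$sgd_loss, alpha = g$sgd_alpha,
                        stringsAsFactors = FALSE)
    # alpha-major order with hinge before modified_huber within each alpha
    penalty <- if (family == "sgd_elasticnet") "elasticnet" else "l2"
    seed <- rng_child_seed(rng)
    fit_predict <- function(Xtr, ytr, Xte) {
      sgd_grid_predict(Xtr, ytr, Xte, grid$loss, grid$alpha, penalty,
                       rng = make_rng(seed))
    }
    sc <- cv_grid_scores(X, y, nrow(grid), fit_predict, k, rng)
    best <- which.max(sc)
    return(list(alpha = grid$alpha[best], loss = grid$loss[best]))
  }
  if (family == "ridge") {
    return(list(alpha = ridge_gcv_alpha(X, y, g$ridge_alpha)))
  }
  defaults
}

# ---- small-d ridge-logistic path (IRLS) -----------------------------------
# glmnet's per-call overhead dominates at nodes with very few features; for
# binary nodes with d <= 64 the L2-penalized logistic path is solved directly
# by warm-started iteratively reweighted least squares. Matches the glmnet
# objective (1/n) * deviance/2-style scaling: loss/n + lambda * ||w||^2 / 2,
# intercept unpenalized.
RIDGE_LOGISTIC_IRLS_MAX_D <- 64L

ridge_logistic_path <- function(X, y01, lambdas, maxit = 25L, tol = 1e-7) {
  n <- nrow(X)
  d <- ncol(X)
  Xa <- cbind(1, X)
  out <- matrix(0, d + 1L, length(lambdas))
  beta <- numeric(d + 1L)
  pen <- diag(c(0, rep(1, d)))
  ord <- order(lambdas, decreasing = TRUE)
  for (li in ord) {
    lam <- lambdas[li]
    for (it in seq_len(maxit)) {
      eta <- drop(Xa %*% beta)
      p <- 1 / (1 + exp(-pmax(pmin(eta, 30), -30)))
      w <- pmax(p * (1 - p), 1e-5)
      grad <- drop(crossprod(Xa, p - y01)) / n + lam * c(0, beta[-1])
      H <- crossprod(Xa * w, Xa) / n + lam * pen
      step <- tryCatch(solve(H, grad), error = function(e) NULL)
      if (is.null(step)) break
      beta <- beta - step
      if (max(abs(step)) < tol) break
    }
    out[, li] <- beta
  }
  out
}

# ---- glmnet helpers -------------------------------------------------------

glmnet_fit <- function(X, y, alpha, lambda) {
  y <- factor(y)
  fam <- if (nlevels(y) > 2L) "multinomial" else "binomial"
  if (ncol(X) < 2L) X <- cbind(X, 0)   # glmnet needs >= 2 columns
  suppressWarnings(
    glmnet::glmnet(X, y, family = fam, alpha = alpha,
                   lambda = sort(unique(lambda), decreasing = TRUE),
                   standardize = FALSE, maxit = 2000L, thresh = 1e-5))
}

glmnet_predict_class <- function(fit, X, lambdas) {
  if (ncol(X) < 2L) X <- cbind(X, 0)
  p <- stats::predict(fit, X, s = lambdas, type = "class")
  if (length(dim(p)) == 3L) p <- p[, 1, ]   # multinomial returns 3-d array
  matrix(as.character(p), nrow = nrow(X))
}

glmnet_weights <- function(fit, lambda, d) {
  cf <- stats::coef(fit, s = lambda)
  if (is.list(cf)) {                      # multinomial: one column per class
    W <- matrix(sapply(cf, function(ci) as.numeric(ci)[-1][seq_len(d)]), nrow = d)
    b <- vapply(cf, function(ci) as.numeric(ci)[1], 0)
    list(W = W, b = b, labels = names(cf))
  } else {                                # binomial: score > 0 -> 2nd level
    v <- as.numeric(cf)
    list(W = matrix(v[-1][seq_len(d)], ncol = 1), b = v[1],
         labels = fit$classnames)
  }
}

# ---- ridge with generalized cross-validation ------------------------------

ridge_gcv_alpha <- function(X, y, alphas) {
  y <- factor(y)
  Y <- stats::model.matrix(~ y - 1) * 2 - 1     # one-hot in {-1, +1}
  xbar <- colMeans(X)
  Xc <- sweep(X, 2, xbar)
  ybar <- colMeans(Y)
  Yc <- sweep(Y, 2, ybar)
  sv <- svd(Xc)
  n <- nrow(X)
  UtY <- crossprod(sv$u, Yc)
  gcv <- sapply(alphas, function(a) {
    shrink <- sv$d^2 / (sv$d^2 + a)
    fitted <- sv$u %*% (shrink * UtY)
    edf <- sum(shrink)
    mean(((Yc - fitted) / (1 - edf / n))^2)
  })
  alphas[which.min(gcv)]
}

ridge_fit <- function(X, y, alpha) {
  y <- factor(y)
  labels <- levels(y)
  Y <- stats::model.matrix(~ y - 1) * 2 - 1
  xbar <- colMeans(X)
  Xc <- sweep(X, 2, xbar)
  ybar <- colMeans(Y)
  Yc <- sweep(Y, 2, ybar)
  sv <- svd(Xc)
  keep <- sv$d > max(sv$d[1], 0) * 1e-10
  dinv <- sv$d[keep] / (sv$d[keep]^2 + alpha)
  W <- sv$v[, keep, drop = FALSE] %*% (dinv * crossprod(sv$u[, keep, drop = FALSE], Yc))
  b <- ybar - drop(crossprod(W, xbar))
  if (length(labels) == 2L) {
    list(W = W[, 2, drop = FALSE] , b = b[2], labels = labels)
  } else {
    list(W = W, b = b, labels = labels)
  }
}

# ---- unified fitted-splitter object ---------------------------------------

new_splitter <- function(family, W, b, labels, feature_idx, params = list()) {
  structure(
    list(family = family, kind = "linear", W = W, b = b,
         branch_labels = labels, feature_idx = feature_idx, params = params,
         achieved_gain = NA_real_),
    class = "landmark_splitter"
  )
}

#' Apply a fitted splitter's partition function
#'
#' Routes each sample to a branch label. Linear splitters score
#' `X[, subset] %*% W + b`; two-class splitters send non-negative scores to
#' the second branch label (points exactly on the hyperplane go to the
#' positive side), multi-class splitters take the arg-max with ties going to
#' the first class in declared order.
#'
#' @param splitter a fitted splitter.
#' @param X full feature matrix (the splitter extracts its own subset).
#' @return character vector of branch labels.
#' @export
predict_splitter <- function(splitter, X) {
  if (splitter$kind == "nnet") return(nnet_predict(splitter, X))
  Xs <- X[, splitter$feature_idx, drop = FALSE]
  S <- Xs %*% splitter$W
  S <- sweep(S, 2, splitter$b, `+`)
  if (ncol(S) == 1L) {
    splitter$branch_labels[1L + (drop(S) >= 0)]
  } else {
    splitter$branch_labels[max.col(S, ties.method = "first")]
  }
}

#' Fit a linear node splitter
#'
#' Fits one of the six linear configurations on a node's samples and returns
#' a self-contained splitter (weights, intercepts, feature subset, branch
#' labels). Families marked as subset users are restricted to
#' `feature_subset`; the L1-logistic and elastic-net SGD families always see
#' the full node feature set. Ridge is only available at nodes with more
#' than 6 samples.
#'
#' @param family splitter family name.
#' @param X node sample matrix (all features).
#' @param y node labels (>= 2 classes).
#' @param feature_subset integer indices of the columns subset-using
#'   families may read; defaults to all columns.
#' @param params hyperparameters from [select_hyperparameters()]; when
#'   `NULL` they are selected (or defaulted) internally.
#' @param rng RNG stream or integer seed.
#' @return a fitted splitter, or `NULL` if the family cannot be fitted on
#'   this node.
#' @export
fit_linear_splitter <- function(family, X, y, feature_subset = NULL,
                                params = NULL, rng = 1L) {
  if (!is.environment(rng)) rng <- make_rng(rng)
  y <- as.character(y)
  if (length(unique(y)) < 2L) stop("single-class node cannot be split")
  info <- splitter_family_info(family)
  if (nrow(X) < info$min_fit) return(NULL)
  d_full <- ncol(X)
  idx <- if (info$subset && !is.null(feature_subset)) {
    sort(feature_subset)
  } else {
    seq_len(d_full)
  }
  Xs <- X[, idx, drop = FALSE]
  if (is.null(params)) {
    params <- if (family == "ridge") {
      list(alpha = ridge_gcv_alpha(Xs, y, splitter_grids()$ridge_alpha))
    } else {
      select_hyperparameters(family, Xs, y, rng)
    }
  }
  fit <- tryCatch(
    switch(family,
      logistic_l2 = , logistic_l1 = {
        alpha <- if (family == "logistic_l1") 1 else 0
        lam <- 1 / (params$C * nrow(Xs))
        labels <- sort(unique(y))
        if (family == "logistic_l2" && length(labels) == 2L &&
            ncol(Xs) <= RIDGE_LOGISTIC_IRLS_MAX_D) {
          B <- ridge_logistic_path(Xs, as.numeric(y == labels[2]), lam)
          list(W = matrix(B[-1, 1], ncol = 1), b = B[1, 1], labels = labels)
        } else {
          lam_seq <- sort(unique(c(lam, lam * c(8, 4, 2))), decreasing = TRUE)
          f <- glmnet_fit(Xs, y, alpha = alpha, lambda = lam_seq)
          glmnet_weights(f, lam, ncol(Xs))
        }
      },
      linear_svc = svc_fit(Xs, y, params$C),
      sgd_l2 = , sgd_elasticnet = {
        penalty <- if (family == "sgd_elasticnet") "elasticnet" else "l2"
        m <- sgd_classifier(Xs, y, loss = params$loss, alpha = params$alpha,
                            penalty = penalty, seed = rng_child_seed(rng))
        list(W = m$W, b = m$b, labels = m$labels)
      },
      ridge = ridge_fit(Xs, y, params$alpha)
    ),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  new_splitter(family, fit$W, fit$b, fit$labels, idx, params)
}

# linear SVC reduced to explicit weights; multiclass handled one-vs-rest so
# the splitter stays a plain weight matrix
svc_fit <- function(X, y, C) {
  labels <- sort(unique(y))
  if (length(labels) == 2L) {
    m <- e1071::svm(X, factor(y, levels = labels), kernel = "linear",
                    cost = C, scale = FALSE, type = "C-classification")
    w <- drop(crossprod(m$coefs, m$SV))
    b <- -m$rho
    # e1071 orients decision values toward its first stored level; flip so
    # score >= 0 means the second of our sorted labels
    pred <- as.character(stats::predict(m, X))
    ours <- labels[1L + ((X %*% w + b) >= 0)]
    if (mean(ours == pred) < 0.5) {
      w <- -w; b <- -b
    }
    list(W = matrix(w, ncol = 1), b = b, labels = labels)
  } else {
    W <- matrix(0, ncol(X), length(labels))
    b <- numeric(length(labels))
    for (k in seq_along(labels)) {
      yk <- ifelse(y == labels[k], "pos", "neg")
      if (length(unique(yk)) < 2L) next
      fk <- svc_fit(X, yk, C)
      W[, k] <- fk$W
      b[k] <- fk$b
    }
    list(W = W, b = b, labels = labels)
  }
}
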