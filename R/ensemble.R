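# Forest construction and decision-space diagnostics: bagged LANDMark trees,
# averaged probability predictions, terminal-leaf proximity, the sqrt(1 - p)
# dissimilarity and principal-coordinates projections.

#' Fit a LANDMark ensemble
#'
#' Builds `control$n_estimators` trees, each on a bootstrap resample of the
#' training set (standard bagging; switchable) with an independent child
#' RNG stream. Per-node randomness (feature subsets, candidate bootstraps,
#' tie-breaking, oracle draws) comes on top of the per-tree bootstrap.
#'
#' @param x training matrix or [feature_table()] (rows = samples).
#' @param y class label per sample (>= 2 classes).
#' @param control a [landmark_control()].
#' @param seed integer seed; fixing it makes the fit reproducible.
#' @return object of class `landmark_ensemble`.
#' @export
landmark <- function(x, y, control = landmark_control(), seed = 1L) {
  if (inherits(x, "feature_table")) x <- x$values
  x <- as.matrix(x)
  y <- as.character(y)
  if (length(y) != nrow(x)) stop("labels do not match sample count")
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("supervised fit requires >= 2 classes")
  rng <- make_rng(seed)
  n <- nrow(x)
  trees <- vector("list", control$n_estimators)
  oob <- vector("list", control$n_estimators)
  for (t in seq_len(control$n_estimators)) {
    child <- make_rng(rng_child_seed(rng))
    if (control$use_bagging) {
      idx <- rng_sample_int(child, n, n, replace = TRUE)
      if (length(unique(y[idx])) < 2L) {
        idx <- rng_sample_int(child, n, n, replace = TRUE)  # one redraw
      }
    } else {
      idx <- seq_len(n)
    }
    trees[[t]] <- build_tree(x[idx, , drop = FALSE], y[idx], control,
                             seed = child, classes = classes)
    oob[[t]] <- setdiff(seq_len(n), idx)
  }
  structure(
    list(trees = trees, classes = classes, n_features = ncol(x),
         feature_ids = colnames(x), control = control, oob = oob,
         seed = seed),
    class = "landmark_ensemble"
  )
}

#' @export
#' @method print landmark_ensemble
print.landmark_ensemble <- function(x, ...) {
  cat(sprintf(
    "landmark_ensemble: %d trees, %d classes, %d features (oracle %s)\n",
    length(x$trees), length(x$classes), x$n_features,
    if (x$control$oracle) "on" else "off"))
  invisible(x)
}

#' Predict from a LANDMark ensemble
#'
#' Class probabilities are the mean of the per-tree leaf distributions;
#' hard labels take the arg-max with ties resolved in favour of the first
#' class in declared order.
#'
#' @param object a `landmark_ensemble`.
#' @param newdata matrix or [feature_table()].
#' @param type `"class"` or `"prob"`.
#' @param ... unused.
#' @return character vector of labels or a probability matrix.
#' @export
predict.landmark_ensemble <- function(object, newdata,
                                      type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "feature_table")) newdata <- newdata$values
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features) {
    stop(sprintf("feature count mismatch: model expects %d, got %d",
                 object$n_features, ncol(newdata)))
  }
  P <- matrix(0, nrow(newdata), length(object$classes))
  for (tree in object$trees) P <- P + predict_tree(tree, newdata)
  P <- P / length(object$trees)
  colnames(P) <- object$classes
  if (type == "prob") return(P)
  object$classes[max.col(P, ties.method = "first")]
}

# per-tree hard labels (arg-max of leaf distribution, ties -> first class)
tree_hard_predictions <- function(ensemble, X) {
  if (inherits(X, "feature_table")) X <- X$values
  sapply(ensemble$trees, function(tr) {
    P <- predict_tree(tr, X)
    ensemble$classes[max.col(P, ties.method = "first")]
  })
}

#' Terminal-leaf proximity matrix
#'
#' Entry (i, j) is the fraction of trees in which samples i and j land in
#' the same terminal leaf; the diagonal is 1 by construction.
#'
#' @param ensemble a fitted `landmark_ensemble`.
#' @param X samples to compare (matrix or [feature_table()]).
#' @return object of class `proximity_matrix` (symmetric matrix in [0, 1]).
#' @export
proximity <- function(ensemble, X) {
  if (inherits(X, "feature_table")) X <- X$values
  X <- as.matrix(X)
  n <- nrow(X)
  counts <- matrix(0, n, n)
  for (tree in ensemble$trees) {
    ids <- apply_tree(tree, X)
    counts <- counts + outer(ids, ids, `==`)
  }
  p <- counts / length(ensemble$trees)
  dimnames(p) <- list(rownames(X), rownames(X))
  structure(p, class = c("proximity_matrix", "matrix"))
}

#' Decision-space dissimilarity from proximities
#'
#' `d(i, j) = sqrt(1 - p(i, j))`: the co-occurrence frequency is subtracted
#' from one and the square root taken, giving a zero-diagonal dissimilarity.
#'
#' @param prox a [proximity()] matrix.
#' @return dissimilarity matrix.
#' @export
proximity_to_dissimilarity <- function(prox) {
  d <- sqrt(pmax(1 - unclass(prox), 0))
  diag(d) <- 0
  d
}

#' Principal coordinates analysis of a dissimilarity matrix
#'
#' Classical scaling: the squared dissimilarities are double-centered,
#' eigendecomposed, and the axes with positive eigenvalues retained.
#' Explained-variance ratios are computed over the positive eigenvalues
#' only (negative eigenvalues are dropped without correction).
#'
#' @param dissimilarity symmetric, zero-diagonal, non-negative matrix (or
#'   `dist`).
#' @return list with `coordinates` (samples x axes) and
#'   `explained_variance_ratio`.
#' @export
pcoa <- function(dissimilarity) {
  d <- as.matrix(dissimilarity)
  if (any(abs(d - t(d)) > 1e-8)) stop("dissimilarity matrix must be symmetric")
  if (any(diag(d) != 0)) stop("dissimilarity matrix must have a zero diagonal")
  if (any(d < 0)) stop("dissimilarities must be non-negative")
  n <- nrow(d)
  fit <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- eig > max(abs(eig)) * 1e-10
  if (!any(pos)) stop("degenerate dissimilarity: no positive eigenvalues")
  k <- sum(pos)
  coords <- fit$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(k))
  list(coordinates = coords,
       explained_variance_ratio = eig[pos] / sum(eig[pos]),
       eigenvalues = eig[pos])
}
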