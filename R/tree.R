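# Single decision-tree construction: a random linear oracle can pre-split
# the root, every other node fits the eligible candidate splitters on (a
# bootstrap of) its samples, scores each candidate's partition of the full
# node by information gain, and picks uniformly among the best.

#' Control parameters for tree and ensemble construction
#'
#' @param n_estimators number of trees in the ensemble.
#' @param max_features fraction of node features drawn as the random subset
#'   offered to subset-using splitters ("randomly selected" families), or
#'   the string `"sqrt"`. Subsets are only drawn at nodes with at least 4
#'   features.
#' @param oracle apply a random linear oracle at the root of every tree, so
#'   each branch leading away from the root is an independently modelled
#'   half-space.
#' @param oracle_probability probability of applying an oracle at non-root
#'   nodes (0 = root only).
#' @param use_nnet offer the neural splitter at nodes with more than 32
#'   samples.
#' @param use_node_bootstrap fit each candidate on a bootstrap resample of
#'   the node's samples (gain is always measured on the full node).
#' @param use_bagging build each tree on a bootstrap resample of the
#'   training set.
#' @param min_samples_split nodes smaller than this become leaves.
#' @param max_depth maximum tree depth (`Inf` = grow to purity).
#' @param gain_epsilon tolerance within which candidate gains are considered
#'   equivalent (random tie-break), and the threshold a split must exceed.
#' @param gain_measure `"entropy"` (Shannon information gain, bits) or
#'   `"gini"`.
#' @param nnet_epochs epoch cap for the neural splitter.
#' @return a `landmark_control` list.
#' @export
landmark_control <- function(n_estimators = 64L, max_features = 0.4,
                             oracle = TRUE, oracle_probability = 0,
                             use_nnet = TRUE, use_node_bootstrap = TRUE,
                             use_bagging = TRUE, min_samples_split = 2L,
                             max_depth = Inf, gain_epsilon = 1e-9,
                             gain_measure = c("entropy", "gini"),
                             nnet_epochs = 300L) {
  gain_measure <- match.arg(gain_measure)
  stopifnot(n_estimators >= 1L)
  structure(list(
    n_estimators = as.integer(n_estimators), max_features = max_features,
    oracle = oracle, oracle_probability = oracle_probability,
    use_nnet = use_nnet, use_node_bootstrap = use_node_bootstrap,
    use_bagging = use_bagging, min_samples_split = min_samples_split,
    max_depth = max_depth, gain_epsilon = gain_epsilon,
    gain_measure = gain_measure, nnet_epochs = nnet_epochs
  ), class = "landmark_control")
}

#' Shannon entropy of a label multiset (bits)
#'
#' @param labels non-empty vector of class labels.
#' @return entropy in bits.
#' @export
entropy <- function(labels) {
  if (length(labels) == 0L) stop("entropy of an empty label set is undefined")
  p <- table(labels) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

gini_impurity <- function(labels) {
  p <- table(labels) / length(labels)
  1 - sum(p^2)
}

#' Information gain of a partition
#'
#' `H(parent) - sum_b (n_b / n) H(branch_b)`, in bits for the entropy
#' measure. Empty branches contribute zero weight.
#'
#' @param parent_labels labels at the node.
#' @param branches partition of `parent_labels`: either a list of label
#'   vectors or a branch assignment vector aligned to `parent_labels`.
#' @param measure `"entropy"` or `"gini"`.
#' @return gain in `[0, H(parent)]`.
#' @export
information_gain <- function(parent_labels, branches, measure = "entropy") {
  imp <- if (measure == "gini") gini_impurity else entropy
  if (!is.list(branches)) branches <- split(parent_labels, branches)
  n <- length(parent_labels)
  child <- sum(vapply(branches, function(b) {
    if (length(b) == 0L) 0 else length(b) / n * imp(b)
  }, 0))
  imp(parent_labels) - child
}

#' Draw a random linear oracle hyperplane
#'
#' Picks two distinct training samples without replacement, takes their
#' midpoint, and uses the difference vector as the hyperplane normal.
#' Samples are partitioned by the side of the hyperplane they fall on;
#' points exactly on the hyperplane go to the positive side.
#'
#' @param X sample matrix (at least two distinct rows).
#' @param rng RNG stream or integer seed.
#' @return an oracle splitter, or `NULL` when all rows are identical
#'   ("oracle unavailable").
#' @export
draw_oracle <- function(X, rng = 1L) {
  if (!is.environment(rng)) rng <- make_rng(rng)
  n <- nrow(X)
  if (n < 2L) return(NULL)
  for (attempt in 1:10) {
    ij <- rng_sample_int(rng, n, 2L)
    a <- X[ij[1], ]
    b <- X[ij[2], ]
    if (any(a != b)) {
      return(structure(
        list(family = "oracle", kind = "oracle",
             midpoint = (a + b) / 2, normal = b - a,
             branch_labels = c("left", "right"),
             feature_idx = seq_len(ncol(X)), params = list(),
             achieved_gain = NA_real_),
        class = "landmark_splitter"))
    }
  }
  NULL
}

oracle_side <- function(splitter, X) {
  s <- drop(sweep(X, 2, splitter$midpoint) %*% splitter$normal)
  ifelse(s >= 0, "right", "left")
}

#' Choose a split among scored candidates
#'
#' All candidates whose gain lies within `gain_epsilon` of the maximum are
#' considered equivalent and one is chosen uniformly at random. Returns
#' `NULL` (leaf signal) when no candidate's gain exceeds `gain_epsilon`.
#'
#' @param candidates list of fitted splitters with `achieved_gain` set.
#' @param rng RNG stream or integer seed.
#' @param gain_epsilon equivalence tolerance.
#' @return the selected splitter or `NULL`.
#' @export
choose_split <- function(candidates, rng = 1L, gain_epsilon = 1e-9) {
  if (!is.environment(rng)) rng <- make_rng(rng)
  if (length(candidates) == 0L) return(NULL)
  gains <- vapply(candidates, function(s) s$achieved_gain, 0)
  if (max(gains) <= gain_epsilon) return(NULL)
  best <- which(gains >= max(gains) - gain_epsilon)
  candidates[[if (length(best) == 1L) best else rng_sample(rng, best, 1L)]]
}

node_bootstrap <- function(X, y, rng) {
  n <- nrow(X)
  for (attempt in 1:10) {
    idx <- rng_sample_int(rng, n, n, replace = TRUE)
    if (length(unique(y[idx])) >= 2L) {
      return(list(X = X[idx, , drop = FALSE], y = y[idx]))
    }
  }
  list(X = X, y = y)
}

# fit all eligible candidates at a node and score their partitions of the
# full node sample set
fit_node_candidates <- function(X, y, control, rng) {
  n <- nrow(X)
  d <- ncol(X)
  subset_idx <- NULL
  if (d >= 4L) {
    m <- if (identical(control$max_features, "sqrt")) {
      ceiling(sqrt(d))
    } else {
      ceiling(control$max_features * d)
    }
    m <- max(1L, min(d, m))
    subset_idx <- sort(rng_sample_int(rng, d, m))
  }
  families <- LINEAR_FAMILIES
  if (n <= 6L) families <- setdiff(families, "ridge")
  candidates <- list()
  for (fam in families) {
    dat <- if (control$use_node_bootstrap) node_bootstrap(X, y, rng) else
      list(X = X, y = y)
    sp <- tryCatch(
      fit_linear_splitter(fam, dat$X, dat$y, feature_subset = subset_idx,
                          params = NULL, rng = rng),
      error = function(e) NULL)
    if (!is.null(sp)) candidates[[length(candidates) + 1L]] <- sp
  }
  if (control$use_nnet && n > 32L) {
    dat <- if (control$use_node_bootstrap) node_bootstrap(X, y, rng) else
      list(X = X, y = y)
    if (nrow(dat$X) > 32L && length(unique(dat$y)) >= 2L) {
      sp <- tryCatch(
        fit_neural_splitter(dat$X, dat$y, rng = rng,
                            feature_subset = subset_idx,
                            epochs = control$nnet_epochs),
        error = function(e) NULL)
      if (!is.null(sp)) candidates[[length(candidates) + 1L]] <- sp
    }
  }
  for (i in seq_along(candidates)) {
    branches <- predict_splitter(candidates[[i]], X)
    candidates[[i]]$achieved_gain <-
      information_gain(y, branches, control$gain_measure)
  }
  candidates
}

#' Build a single LANDMark decision tree
#'
#' @param X training sample matrix.
#' @param y class label per row (>= 2 classes).
#' @param control a [landmark_control()].
#' @param seed integer seed (or RNG stream).
#' @param classes optional fixed class ordering (used by the ensemble).
#' @return object of class `landmark_tree`.
#' @export
build_tree <- function(X, y, control = landmark_control(), seed = 1L,
                       classes = NULL) {
  rng <- if (is.environment(seed)) seed else make_rng(seed)
  X <- as.matrix(X)
  y <- as.character(y)
  if (is.null(classes)) classes <- sort(unique(y))
  counter <- new.env(parent = emptyenv())
  counter$next_id <- 1L

  class_dist <- function(yy) {
    tab <- table(factor(yy, levels = classes))
    as.numeric(tab) / length(yy)
  }

  grow <- function(X, y, depth, at_root) {
    id <- counter$next_id
    counter$next_id <- id + 1L
    node <- list(id = id, depth = depth, n_train = length(y),
                 class_distribution = stats::setNames(class_dist(y), classes),
                 splitter = NULL, children = NULL, majority_child = NULL)
    pure <- length(unique(y)) < 2L
    if (pure || length(y) < control$min_samples_split ||
        depth >= control$max_depth) {
      return(node)
    }
    use_oracle <- (at_root && control$oracle) ||
      (!at_root && control$oracle_probability > 0 &&
         rng_runif(rng, 1) < control$oracle_probability)
    splitter <- NULL
    if (use_oracle) {
      splitter <- draw_oracle(X, rng)
      if (!is.null(splitter)) {
        branches <- oracle_side(splitter, X)
        if (length(unique(branches)) < 2L) splitter <- NULL else
          splitter$achieved_gain <-
            information_gain(y, branches, control$gain_measure)
      }
    }
    if (is.null(splitter)) {
      candidates <- fit_node_candidates(X, y, control, rng)
      splitter <- choose_split(candidates, rng, control$gain_epsilon)
      if (is.null(splitter)) return(node)
      branches <- predict_splitter(splitter, X)
    }
    node$splitter <- splitter
    groups <- split(seq_along(y), branches)
    node$children <- lapply(groups, function(ix) {
      grow(X[ix, , drop = FALSE], y[ix], depth + 1L, FALSE)
    })
    sizes <- vapply(groups, length, 0L)
    node$majority_child <- names(groups)[which.max(sizes)]
    node
  }

  root <- grow(X, y, 0L, TRUE)
  structure(
    list(root = root, classes = classes, n_features = ncol(X),
         control = control),
    class = "landmark_tree"
  )
}

route_tree <- function(node, X, idx, assign_fun) {
  if (is.null(node$splitter)) {
    assign_fun(node, idx)
    return(invisible(NULL))
  }
  branches <- if (node$splitter$kind == "oracle") {
    oracle_side(node$splitter, X[idx, , drop = FALSE])
  } else {
    predict_splitter(node$splitter, X[idx, , drop = FALSE])
  }
  known <- names(node$children)
  branches[!branches %in% known] <- node$majority_child
  for (b in unique(branches)) {
    route_tree(node$children[[b]], X, idx[branches == b], assign_fun)
  }
  invisible(NULL)
}

#' Predict class probabilities with a single tree
#'
#' Each sample is routed to a terminal leaf and receives that leaf's class
#' distribution. Branch labels unseen in training route to the child that
#' received the most training samples.
#'
#' @param tree a `landmark_tree`.
#' @param X matrix with the training feature count.
#' @return samples-by-classes probability matrix.
#' @export
predict_tree <- function(tree, X) {
  X <- as.matrix(X)
  if (ncol(X) != tree$n_features) {
    stop(sprintf("feature count mismatch: tree expects %d, got %d",
                 tree$n_features, ncol(X)))
  }
  P <- matrix(NA_real_, nrow(X), length(tree$classes),
              dimnames = list(rownames(X), tree$classes))
  route_tree(tree$root, X, seq_len(nrow(X)), function(node, idx) {
    P[idx, ] <<- matrix(node$class_distribution, length(idx),
                        length(tree$classes), byrow = TRUE)
  })
  P
}

#' Terminal leaf assignment of a single tree
#'
#' @inheritParams predict_tree
#' @return integer vector of terminal node ids, one per sample.
#' @export
apply_tree <- function(tree, X) {
  X <- as.matrix(X)
  if (ncol(X) != tree$n_features) {
    stop(sprintf("feature count mismatch: tree expects %d, got %d",
                 tree$n_features, ncol(X)))
  }
  ids <- integer(nrow(X))
  route_tree(tree$root, X, seq_len(nrow(X)), function(node, idx) {
    ids[idx] <<- node$id
  })
  ids
}

tree_leaf_ids <- function(tree) {
  collect <- function(node) {
    if (is.null(node$splitter)) return(node$id)
    unlist(lapply(node$children, collect), use.names = FALSE)
  }
  collect(tree$root)
}

#' @export
#' @method print landmark_tree
print.landmark_tree <- function(x, ...) {
  n_leaves <- length(tree_leaf_ids(x))
  cat(sprintf("landmark_tree: %d classes, %d features, %d leaves\n",
              length(x$classes), x$n_features, n_leaves))
  invisible(x)
}
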