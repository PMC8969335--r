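# Evaluation statistics: the confusion-matrix balanced accuracy variant used
# throughout the benchmarking harness, mean-recall balanced accuracy,
# feature-recovery Matthews correlation, Cohen's kappa, kappa-error pair
# statistics, Spearman rank consistency and Jaccard distance.

#' Confusion matrix
#'
#' @param truth true labels.
#' @param predicted predicted labels.
#' @param classes class ordering (defaults to the sorted union).
#' @return square integer matrix, rows = truth, columns = prediction.
#' @export
confusion_matrix <- function(truth, predicted, classes = NULL) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length")
  }
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  table(factor(truth, levels = classes),
        factor(predicted, levels = classes))
}

#' Balanced accuracy (confusion-matrix max-marginal form)
#'
#' For each class the diagonal count is divided by the *greater* of the
#' class's row or column sum, and the results are averaged over classes.
#' This is deliberately not the common mean-recall definition (see
#' [balanced_accuracy_recall()]): dividing by the larger marginal penalizes
#' both missed samples and over-prediction of a class. Classes absent from
#' both margins are excluded from the average.
#'
#' @param cm a [confusion_matrix()] (or any square count matrix).
#' @return score in [0, 1].
#' @export
balanced_accuracy <- function(cm) {
  cm <- unclass(as.matrix(cm))
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  if (sum(cm) == 0) stop("empty confusion matrix")
  rs <- rowSums(cm)
  cs <- colSums(cm)
  active <- rs + cs > 0
  mean(diag(cm)[active] / pmax(rs[active], cs[active]))
}

#' Balanced accuracy (mean per-class recall)
#'
#' The standard definition: the average of the per-class recalls
#' (diagonal over row sum), over classes present in the truth.
#'
#' @inheritParams balanced_accuracy
#' @return score in [0, 1].
#' @export
balanced_accuracy_recall <- function(cm) {
  cm <- unclass(as.matrix(cm))
  if (sum(cm) == 0) stop("empty confusion matrix")
  rs <- rowSums(cm)
  mean(diag(cm)[rs > 0] / rs[rs > 0])
}

#' Feature-recovery Matthews correlation coefficient
#'
#' Scores a selected feature set against the ground-truth set of truly
#' perturbed features over a feature universe, via the 2x2 counts
#' TP/FP/FN/TN and
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' A zero factor in the denominator yields 0 by convention.
#'
#' @param selected selected feature identifiers (or indices).
#' @param truth ground-truth feature identifiers (or indices).
#' @param universe all feature identifiers, or the universe size.
#' @return MCC in [-1, 1].
#' @export
mcc_feature_recovery <- function(selected, truth, universe) {
  if (length(universe) == 1L && is.numeric(universe)) {
    universe_size <- universe
  } else {
    selected <- intersect(selected, universe)
    truth <- intersect(truth, universe)
    universe_size <- length(universe)
  }
  tp <- length(intersect(selected, truth))
  fp <- length(setdiff(selected, truth))
  fn <- length(setdiff(truth, selected))
  tn <- universe_size - tp - fp - fn
  num <- tp * tn - fp * fn
  den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  if (den == 0) return(0)
  num / den
}

#' Cohen's kappa between two labelings
#'
#' `(p_o - p_e) / (1 - p_e)` with the expected agreement from marginal
#' products. When `p_e = 1` (both raters constant and identical margins)
#' kappa is defined as 1 if the observed agreement is also perfect, else 0.
#'
#' @param pred_a,pred_b equal-length label vectors.
#' @return kappa in [-1, 1].
#' @export
cohen_kappa <- function(pred_a, pred_b) {
  pred_a <- as.character(pred_a)
  pred_b <- as.character(pred_b)
  if (length(pred_a) != length(pred_b)) stop("label vectors differ in length")
  n <- length(pred_a)
  classes <- sort(unique(c(pred_a, pred_b)))
  cm <- table(factor(pred_a, levels = classes),
              factor(pred_b, levels = classes)) / n
  po <- sum(diag(cm))
  pe <- sum(rowSums(cm) * colSums(cm))
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    return(if (po >= 1 - .Machine$double.eps^0.5) 1 else 0)
  }
  (po - pe) / (1 - pe)
}

#' Kappa-error points for an ensemble
#'
#' One point per unordered pair of trees: the x-coordinate is Cohen's kappa
#' between the two trees' hard predictions on the evaluation set, the
#' y-coordinate the mean of the two trees' individual error rates.
#'
#' @param ensemble a fitted `landmark_ensemble`.
#' @param X evaluation samples.
#' @param y true labels.
#' @return data frame with columns `tree_i`, `tree_j`, `kappa`,
#'   `mean_pair_error`.
#' @export
kappa_error_points <- function(ensemble, X, y) {
  y <- as.character(y)
  preds <- tree_hard_predictions(ensemble, X)
  errors <- colMeans(preds != y)
  t_n <- ncol(preds)
  pairs <- utils::combn(t_n, 2)
  data.frame(
    tree_i = pairs[1, ], tree_j = pairs[2, ],
    kappa = apply(pairs, 2, function(p) cohen_kappa(preds[, p[1]], preds[, p[2]])),
    mean_pair_error = apply(pairs, 2, function(p) mean(errors[p]))
  )
}

#' Spearman rank consistency of two importance vectors
#'
#' Spearman's rho with average ranks for ties; eliminated features are
#' expected to carry importance exactly 0 before ranking. Constant vectors
#' have no defined rank correlation and return `NA` with a warning.
#'
#' @param importance_a,importance_b aligned numeric vectors.
#' @return rho in [-1, 1], or `NA`.
#' @export
spearman_rank_consistency <- function(importance_a, importance_b) {
  if (length(importance_a) != length(importance_b)) {
    stop("importance vectors differ in length")
  }
  if (stats::sd(importance_a) == 0 || stats::sd(importance_b) == 0) {
    warning("rank correlation undefined for a constant importance vector")
    return(NA_real_)
  }
  stats::cor(importance_a, importance_b, method = "spearman")
}

#' Jaccard distance between two feature sets
#'
#' `1 - |A intersect B| / |A union B|`; two empty sets have distance 0.
#'
#' @param set_a,set_b vectors treated as sets.
#' @return distance in [0, 1].
#' @export
jaccard_distance <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  u <- length(union(set_a, set_b))
  if (u == 0L) return(0)
  1 - length(intersect(set_a, set_b)) / u
}
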