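# Feature importances for the splitter-based ensemble: each internal node's
# information gain, weighted by the fraction of training samples reaching
# the node, is distributed over the features its splitter reads --
# proportionally to absolute coefficients for linear splitters, uniformly
# for oracle and neural nodes -- then summed over the forest and normalized.

#' Gain-attribution feature importance of a LANDMark ensemble
#'
#' @param ensemble a fitted `landmark_ensemble`.
#' @return named non-negative vector over the training features, summing to
#'   1 when any split exists.
#' @export
landmark_importance <- function(ensemble) {
  d <- ensemble$n_features
  total <- numeric(d)
  for (tree in ensemble$trees) {
    n_root <- tree$root$n_train
    walk <- function(node) {
      if (is.null(node$splitter)) return(invisible(NULL))
      sp <- node$splitter
      mass <- sp$achieved_gain * node$n_train / n_root
      if (is.finite(mass) && mass > 0) {
        idx <- sp$feature_idx
        w <- if (sp$kind == "linear") {
          a <- rowSums(abs(as.matrix(sp$W)))
          if (sum(a) == 0) rep(1, length(idx)) else a
        } else {
          rep(1, length(idx))
        }
        total[idx] <<- total[idx] + mass * w / sum(w)
      }
      lapply(node$children, walk)
      invisible(NULL)
    }
    walk(tree$root)
  }
  if (sum(total) > 0) total <- total / sum(total)
  names(total) <- ensemble$feature_ids %||% paste0("F", seq_len(d))
  total
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# |coefficient| importance of a plain linear model (W is d x k or d x 1)
coef_importance <- function(W, feature_ids = NULL) {
  v <- rowSums(abs(as.matrix(W)))
  if (!is.null(feature_ids)) names(v) <- feature_ids
  v
}
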