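# Recursive feature elimination: iteratively refit a model, score features,
# and drop the weakest fraction until the target set size remains.

#' Recursive feature elimination
#'
#' At each iteration the model factory is refitted on the surviving
#' features, features are scored by the model's importance, and the lowest
#' `ceiling(step_fraction * remaining)` are dropped -- never crossing below
#' `n_keep`. The returned `elimination_order` ranks all features from most
#' important (the final survivors, ordered by the last model's importance)
#' to least (earliest eliminated).
#'
#' @param model_factory function `(x, y, seed)` returning a fitted model
#'   wrapper with an `importance` element (see [model_registry()]), or a
#'   family name from the registry.
#' @param x feature matrix or [feature_table()].
#' @param y class labels.
#' @param n_keep target number of surviving features (100 in the standard
#'   biomarker workflow).
#' @param step_fraction fraction of remaining features dropped per
#'   iteration.
#' @param seed integer seed passed to each refit.
#' @return object of class `rfe_result` with `selected` (ordered ids),
#'   `elimination_order`, `importance` (final scores, eliminated = 0) and
#'   `n_iterations`.
#' @export
rfe_select <- function(model_factory, x, y, n_keep = 100L,
                       step_fraction = 0.1, seed = 1L) {
  if (is.character(model_factory)) {
    model_factory <- model_registry()[[model_factory]]
    if (is.null(model_factory)) stop("unknown model family")
  }
  if (inherits(x, "feature_table")) x <- x$values
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("F", seq_len(ncol(x)))
  d <- ncol(x)
  if (n_keep >= d) stop("n_keep must be smaller than the feature count")
  surviving <- colnames(x)
  eliminated <- character(0)   # worst dropped first; stored worst-last order
  n_iter <- 0L
  final_imp <- NULL
  repeat {
    n_iter <- n_iter + 1L
    fit <- model_factory(x[, surviving, drop = FALSE], y, seed)
    imp <- fit$importance
    if (is.null(imp)) {
      stop("model family provides no feature importances for RFE")
    }
    imp <- imp[surviving]
    if (length(surviving) == n_keep) {
      final_imp <- imp
      break
    }
    n_drop <- min(ceiling(step_fraction * length(surviving)),
                  length(surviving) - n_keep)
    ord <- order(imp, decreasing = FALSE)
    drop_ids <- surviving[ord[seq_len(n_drop)]]
    eliminated <- c(rev(drop_ids), eliminated)
    surviving <- setdiff(surviving, drop_ids)
  }
  selected <- surviving[order(final_imp, decreasing = TRUE)]
  importance <- stats::setNames(numeric(d), colnames(x))
  importance[selected] <- final_imp[selected]
  structure(
    list(selected = selected,
         elimination_order = c(selected, eliminated),
         importance = importance,
         n_iterations = n_iter),
    class = "rfe_result"
  )
}

#' @export
#' @method print rfe_result
print.rfe_result <- function(x, ...) {
  cat(sprintf("rfe_result: %d features selected in %d iterations\n",
              length(x$selected), x$n_iterations))
  invisible(x)
}
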