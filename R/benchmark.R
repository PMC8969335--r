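# Multi-model benchmarking harness: a registry of classifier families
# (splitter ensembles, axis-aligned forests, regularized linear models),
# repeated stratified train/test evaluation with the confusion-matrix
# balanced accuracy, top-k feature-recovery scoring against synthetic
# ground truth, and the half-split rank-consistency experiment.

#' Registry of benchmark model families
#'
#' Each entry is a factory `(x, y, seed)` returning a wrapper with elements
#' `predict(newx)` (labels), `prob(newx)` (probability matrix or `NULL`)
#' and `importance` (named non-negative vector over the training features).
#' Families: `landmark_oracle`, `landmark` (no oracle), `random_forest`,
#' `extra_trees` (both via ranger, 100 trees, impurity importance),
#' `linear_svc`, `logistic`, `ridge`, `sgd_mh` and `sgd_sh`
#' (modified-Huber / squared-hinge stochastic-gradient linear models).
#' Regularization for the linear families is chosen by stratified
#' cross-validated grid search over logarithmically spaced values in
#' `[1e-4, 1e4]` (generalized cross-validation in `[1e-3, 1e4]` for ridge).
#'
#' @param control a [landmark_control()] used by the two splitter ensemble
#'   families (neural splitter off by default here: the harness favours
#'   many repeats over per-node network training).
#' @return named list of factories.
#' @export
model_registry <- function(control = NULL) {
  lm_ctl <- control %||% landmark_control(use_nnet = FALSE)
  lm_ctl_no <- lm_ctl
  lm_ctl_no$oracle <- FALSE
  lm_ctl_or <- lm_ctl
  lm_ctl_or$oracle <- TRUE

  landmark_factory <- function(ctl) {
    force(ctl)
    function(x, y, seed = 1L) {
      fit <- landmark(x, y, control = ctl, seed = seed)
      list(model = fit,
           predict = function(newx) predict(fit, newx, type = "class"),
           prob = function(newx) predict(fit, newx, type = "prob"),
           importance = landmark_importance(fit))
    }
  }
  ranger_factory <- function(extra_trees) {
    force(extra_trees)
    function(x, y, seed = 1L) {
      df_x <- as.data.frame(x)
      colnames(df_x) <- make.names(colnames(df_x), unique = TRUE)
      args <- list(x = df_x, y = factor(y), num.trees = 100L,
                   importance = "impurity", seed = seed %% .Machine$integer.max,
                   probability = TRUE, num.threads = 1L)
      if (extra_trees) {
        args$splitrule <- "extratrees"
        args$replace <- FALSE
        args$sample.fraction <- 1
      }
      fit <- do.call(ranger::ranger, args)
      classes <- colnames(fit$predictions)
      imp <- fit$variable.importance
      names(imp) <- colnames(x)
      list(model = fit,
           predict = function(newx) {
             ndf <- as.data.frame(newx)
             colnames(ndf) <- colnames(df_x)
             p <- stats::predict(fit, ndf, num.threads = 1L)$predictions
             classes[max.col(p, ties.method = "first")]
           },
           prob = function(newx) {
             ndf <- as.data.frame(newx)
             colnames(ndf) <- colnames(df_x)
             stats::predict(fit, ndf, num.threads = 1L)$predictions
           },
           importance = pmax(imp, 0))
    }
  }
  linear_wrap <- function(W, b, labels, feature_ids) {
    list(predict = function(newx) {
      S <- sweep(as.matrix(newx) %*% W, 2, b, `+`)
      if (ncol(S) == 1L) labels[1L + (drop(S) >= 0)]
      else labels[max.col(S, ties.method = "first")]
    },
    prob = NULL,
    importance = coef_importance(W, feature_ids))
  }
  svc_factory <- function(x, y, seed = 1L) {
    rng <- make_rng(seed)
    Cs <- 10^seq(-4, 4)
    k <- min(5L, min(table(y)))
    C <- if (k >= 2L) {
      sc <- cv_grid_scores(as.matrix(x), as.character(y), length(Cs),
                           function(Xtr, ytr, Xte) {
                             sapply(Cs, function(C) {
                               m <- tryCatch(e1071::svm(Xtr, factor(ytr),
                                                        kernel = "linear", cost = C,
                                                        scale = FALSE,
                                                        type = "C-classification"),
                                             error = function(e) NULL)
                               if (is.null(m)) rep(names(which.max(table(ytr))), nrow(Xte))
                               else as.character(stats::predict(m, Xte))
                             })
                           }, k, rng)
      Cs[which.max(sc)]
    } else 1
    f <- svc_fit(as.matrix(x), as.character(y), C)
    c(linear_wrap(f$W, f$b, f$labels, colnames(x)), list(model = f))
  }
  logistic_factory <- function(x, y, seed = 1L) {
    rng <- make_rng(seed)
    p <- select_hyperparameters("logistic_l2", as.matrix(x),
                                as.character(y), rng)
    sp <- fit_linear_splitter("logistic_l2", as.matrix(x), as.character(y),
                              params = p, rng = rng)
    c(linear_wrap(sp$W, sp$b, sp$branch_labels, colnames(x)),
      list(model = sp))
  }
  ridge_factory <- function(x, y, seed = 1L) {
    a <- ridge_gcv_alpha(as.matrix(x), as.character(y),
                         splitter_grids()$ridge_alpha)
    f <- ridge_fit(as.matrix(x), as.character(y), a)
    c(linear_wrap(f$W, f$b, f$labels, colnames(x)), list(model = f))
  }
  sgd_factory <- function(loss) {
    force(loss)
    function(x, y, seed = 1L) {
      rng <- make_rng(seed)
      alphas <- 10^seq(-4, 4)
      k <- min(5L, min(table(y)))
      alpha <- if (k >= 2L) {
        cv_seed <- rng_child_seed(rng)
        sc <- cv_grid_scores(as.matrix(x), as.character(y), length(alphas),
                             function(Xtr, ytr, Xte) {
                               sgd_grid_predict(Xtr, ytr, Xte,
                                                rep(loss, length(alphas)),
                                                alphas, "l2",
                                                rng = make_rng(cv_seed))
                             }, k, rng)
        alphas[which.max(sc)]
      } else 1e-3
      m <- sgd_classifier(as.matrix(x), as.character(y), loss = loss,
                          alpha = alpha, penalty = "l2",
                          seed = rng_child_seed(rng))
      c(linear_wrap(m$W, m$b, m$labels, colnames(x)), list(model = m))
    }
  }
  list(
    landmark_oracle = landmark_factory(lm_ctl_or),
    landmark = landmark_factory(lm_ctl_no),
    random_forest = ranger_factory(FALSE),
    extra_trees = ranger_factory(TRUE),
    linear_svc = svc_factory,
    logistic = logistic_factory,
    ridge = ridge_factory,
    sgd_mh = sgd_factory("modified_huber"),
    sgd_sh = sgd_factory("squared_hinge")
  )
}

as_benchmark_dataset <- function(ds) {
  if (inherits(ds, "synthetic_dataset")) {
    list(x = ds$table$values, y = ds$labels, truth = ds$truth)
  } else if (is.list(ds) && !is.null(ds$x) && !is.null(ds$y)) {
    x <- if (inherits(ds$x, "feature_table")) ds$x$values else as.matrix(ds$x)
    list(x = x, y = as.character(ds$y), truth = ds$truth)
  } else {
    stop("datasets must be synthetic_dataset objects or lists with x and y")
  }
}

#' Repeated train/test benchmark over datasets and model families
#'
#' For every dataset, family and repeat: fit on the stratified training
#' split (the repeat's seed is its iteration number), score the test split
#' with the confusion-matrix balanced accuracy, and -- when the dataset
#' carries ground-truth perturbed features -- extract the model's top-k
#' features (k = number of true features) and score recovery with the
#' Matthews correlation coefficient.
#'
#' @param datasets named list of `synthetic_dataset` objects or lists with
#'   `x`, `y` and optional `truth`.
#' @param families character vector of [model_registry()] names, or a named
#'   list of factories.
#' @param n_repeats repeats per dataset (30 in the standard design).
#' @param test_fraction held-out fraction (0.2 in the standard design).
#' @param seed_offset added to each repeat's iteration-number seed.
#' @param registry optional registry (defaults to [model_registry()]).
#' @return tidy data frame: dataset, family, repeat index, seed, balanced
#'   accuracy `score`, `mcc` (NA without ground truth), `error` message for
#'   failed cells.
#' @export
run_benchmark <- function(datasets, families, n_repeats = 30L,
                          test_fraction = 0.2, seed_offset = 0L,
                          registry = NULL) {
  if (is.null(registry)) registry <- model_registry()
  factories <- if (is.list(families)) families else {
    missing <- setdiff(families, names(registry))
    if (length(missing) > 0L) {
      stop("unknown model families: ", paste(missing, collapse = ", "))
    }
    registry[families]
  }
  if (is.null(names(datasets))) {
    names(datasets) <- paste0("dataset", seq_along(datasets))
  }
  rows <- list()
  for (ds_name in names(datasets)) {
    ds <- as_benchmark_dataset(datasets[[ds_name]])
    schedule <- stratified_splits(ds$y, test_fraction, n_repeats, seed_offset)
    for (fam in names(factories)) {
      for (i in seq_along(schedule$repeats)) {
        rep_i <- schedule$repeats[[i]]
        row <- data.frame(dataset = ds_name, family = fam, rep = i,
                          seed = rep_i$seed, score = NA_real_,
                          mcc = NA_real_, error = NA_character_,
                          stringsAsFactors = FALSE)
        res <- tryCatch({
          fit <- factories[[fam]](ds$x[rep_i$train, , drop = FALSE],
                                  ds$y[rep_i$train], seed = rep_i$seed)
          pred <- fit$predict(ds$x[rep_i$test, , drop = FALSE])
          cm <- confusion_matrix(ds$y[rep_i$test], pred,
                                 classes = sort(unique(ds$y)))
          row$score <- balanced_accuracy(cm)
          if (!is.null(ds$truth)) {
            k <- length(ds$truth)
            imp <- fit$importance
            top <- names(sort(imp, decreasing = TRUE))[seq_len(k)]
            row$mcc <- mcc_feature_recovery(top, ds$truth, ncol(ds$x))
          }
          row
        }, error = function(e) {
          row$error <- conditionMessage(e)
          row
        })
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  do.call(rbind, rows)
}

#' Half-split rank-consistency experiment
#'
#' Per repeat (seed = iteration number) the data are split into two
#' stratified halves. On each half a full model is fitted and scored on the
#' opposite half; recursive feature elimination reduces each half to
#' `n_keep` features; reduced models are refitted and scored; importance
#' vectors over all features (eliminated features scored exactly 0) are
#' compared between halves by Spearman's rho, and the selected sets by
#' Jaccard distance.
#'
#' @param x feature matrix or [feature_table()].
#' @param y class labels (each class needs >= 4 samples).
#' @param families registry family names or named factory list.
#' @param n_repeats number of random half-splits (30 in the standard
#'   design).
#' @param n_keep features retained by RFE (100 in the standard workflow).
#' @param step_fraction RFE step.
#' @param seed_offset added to iteration-number seeds.
#' @param registry optional [model_registry()].
#' @return list with `scores` (full/reduced balanced accuracies per half)
#'   and `consistency` (per repeat: `rho`, `jaccard`).
#' @export
half_split_consistency_experiment <- function(x, y, families,
                                              n_repeats = 30L, n_keep = 100L,
                                              step_fraction = 0.1,
                                              seed_offset = 0L,
                                              registry = NULL) {
  if (is.null(registry)) registry <- model_registry()
  factories <- if (is.list(families)) families else registry[families]
  if (inherits(x, "feature_table")) x <- x$values
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("F", seq_len(ncol(x)))
  y <- as.character(y)
  if (min(table(y)) < 4L) stop("each class needs at least 4 samples")
  schedule <- stratified_splits(y, 0.5, n_repeats, seed_offset)
  score_rows <- list()
  cons_rows <- list()
  for (i in seq_along(schedule$repeats)) {
    rep_i <- schedule$repeats[[i]]
    halves <- list(rep_i$train, rep_i$test)
    for (fam in names(factories)) {
      sel <- vector("list", 2)
      imp <- vector("list", 2)
      ok <- TRUE
      for (h in 1:2) {
        tr <- halves[[h]]
        te <- halves[[3 - h]]
        res <- tryCatch({
          full <- factories[[fam]](x[tr, , drop = FALSE], y[tr],
                                   seed = rep_i$seed)
          full_score <- balanced_accuracy(confusion_matrix(
            y[te], full$predict(x[te, , drop = FALSE]),
            classes = sort(unique(y))))
          rfe <- rfe_select(factories[[fam]], x[tr, , drop = FALSE], y[tr],
                            n_keep = n_keep, step_fraction = step_fraction,
                            seed = rep_i$seed)
          red <- factories[[fam]](x[tr, rfe$selected, drop = FALSE], y[tr],
                                  seed = rep_i$seed)
          red_score <- balanced_accuracy(confusion_matrix(
            y[te], red$predict(x[te, rfe$selected, drop = FALSE]),
            classes = sort(unique(y))))
          imp_vec <- stats::setNames(numeric(ncol(x)), colnames(x))
          imp_vec[rfe$selected] <- red$importance[rfe$selected]
          list(full_score = full_score, red_score = red_score,
               selected = rfe$selected, importance = imp_vec)
        }, error = function(e) NULL)
        if (is.null(res)) { ok <- FALSE; break }
        sel[[h]] <- res$selected
        imp[[h]] <- res$importance
        score_rows[[length(score_rows) + 1L]] <- data.frame(
          family = fam, rep = i, half = h, full_score = res$full_score,
          reduced_score = res$red_score, stringsAsFactors = FALSE)
      }
      if (ok) {
        rho <- suppressWarnings(
          spearman_rank_consistency(imp[[1]], imp[[2]]))
        cons_rows[[length(cons_rows) + 1L]] <- data.frame(
          family = fam, rep = i, rho = rho,
          jaccard = jaccard_distance(sel[[1]], sel[[2]]),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(scores = do.call(rbind, score_rows),
       consistency = do.call(rbind, cons_rows))
}
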