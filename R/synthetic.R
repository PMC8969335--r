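# Synthetic presence-absence generator with known ground truth.
#
# A control group is drawn feature-wise Bernoulli from baseline occurrence
# probabilities; a treatment group shares the baseline except for a chosen
# set of features whose presence odds are shifted by a log-odds likelihood
# multiplier, after which a small fraction of feature columns is randomly
# shuffled across all samples to inject label-free noise.

#' Perturbation design for synthetic presence-absence data
#'
#' Defaults follow the standard study design: 24 control and 24 treatment
#' samples, likelihood multipliers drawn per perturbed feature from
#' {0.1, 0.125, 0.25, 0.5, 2, 4, 8, 10}, and 5% of feature columns
#' shuffled.
#'
#' @param n_perturbed number of truly perturbed features (25, 50 or 75 in
#'   the standard scenarios).
#' @param likelihood_choices positive multipliers applied to baseline
#'   presence odds.
#' @param shuffle_fraction fraction of features whose columns are permuted
#'   across all samples after generation.
#' @param n_control,n_treatment group sizes.
#' @return a `perturbation_spec` list.
#' @export
perturbation_spec <- function(n_perturbed = 25L,
                              likelihood_choices = c(0.1, 0.125, 0.25, 0.5,
                                                     2, 4, 8, 10),
                              shuffle_fraction = 0.05,
                              n_control = 24L, n_treatment = 24L) {
  stopifnot(all(likelihood_choices > 0),
            shuffle_fraction >= 0, shuffle_fraction <= 1,
            n_perturbed >= 1, n_control >= 1, n_treatment >= 1)
  structure(list(n_perturbed = as.integer(n_perturbed),
                 likelihood_choices = likelihood_choices,
                 shuffle_fraction = shuffle_fraction,
                 n_control = as.integer(n_control),
                 n_treatment = as.integer(n_treatment)),
            class = "perturbation_spec")
}

#' Estimate baseline occurrence probabilities from a binary table
#'
#' Per-feature occurrence frequency across samples, clipped to
#' `[1/(2n), 1 - 1/(2n)]` so that all-absent or all-present features keep
#' finite log-odds.
#'
#' @param table a binary [feature_table()].
#' @return named vector of probabilities in (0, 1).
#' @export
estimate_baseline_probs <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (!table$is_binary) stop("baseline probabilities require a binary table")
  n <- nrow(table$values)
  p <- colMeans(table$values)
  pmin(pmax(p, 1 / (2 * n)), 1 - 1 / (2 * n))
}

#' Shift a presence probability by a likelihood multiplier
#'
#' Solves `log(q / (1 - q)) = log(p_o / (1 - p_o)) + log(p_n)` for `q`:
#' the perturbed probability is
#' `q = p_o * p_n / (1 - p_o + p_o * p_n)`.
#'
#' @param p_o baseline probability in (0, 1).
#' @param p_n positive likelihood multiplier on the odds.
#' @return perturbed probability `q` in (0, 1). Vectorized.
#' @export
perturb_probability <- function(p_o, p_n) {
  if (any(p_o <= 0 | p_o >= 1)) stop("p_o must lie strictly in (0, 1)")
  if (any(p_n <= 0)) stop("p_n must be positive")
  p_o * p_n / (1 - p_o + p_o * p_n)
}

#' Self-contained baseline occurrence profile
#'
#' Draws per-feature baseline probabilities from a Beta sparsity profile
#' emulating a *filtered* presence-absence ASV table: most features are
#' rare, a few are common (default Beta(0.5, 2.83), mean occupancy ~ 0.15
#' before truncation). Because baseline frequencies are estimated from a
#' table already filtered to features present in at least `min_prevalence`
#' of `n_ref` samples, the profile is truncated below the implied floor
#' `min_prevalence / n_ref` (by inverse-CDF truncation, avoiding an atom at
#' the floor) and clipped above at `1 - 1/(2 n_ref)`.
#'
#' @param n_features number of features.
#' @param shape1,shape2 Beta parameters of the sparsity profile.
#' @param min_prevalence,n_ref prevalence filter (in samples) and reference
#'   table size implying the occurrence-frequency floor.
#' @param seed integer seed or RNG stream.
#' @return named probability vector.
#' @export
generate_baseline <- function(n_features, shape1 = 0.5, shape2 = 2.8333,
                              min_prevalence = 2L, n_ref = 24L, seed = 1L) {
  stopifnot(n_features >= 1)
  rng <- if (is.environment(seed)) seed else make_rng(seed)
  floor_p <- min_prevalence / n_ref
  u <- rng_runif(rng, n_features)
  lo <- stats::pbeta(floor_p, shape1, shape2)
  p <- stats::qbeta(lo + u * (1 - lo), shape1, shape2)
  p <- pmin(p, 1 - 1 / (2 * n_ref))
  stats::setNames(p, paste0("ASV", seq_len(n_features)))
}

#' Generate a synthetic presence-absence dataset with ground truth
#'
#' Control samples are feature-wise Bernoulli draws from the baseline
#' probabilities. Treatment samples share the baseline except for
#' `spec$n_perturbed` randomly chosen features, whose presence probability
#' is shifted by a likelihood multiplier drawn per feature from
#' `spec$likelihood_choices` (via [perturb_probability()]). Finally
#' `ceiling(shuffle_fraction * d)` randomly chosen feature columns are
#' permuted across all samples.
#'
#' @param baseline_probs per-feature baseline probabilities.
#' @param spec a [perturbation_spec()].
#' @param seed integer seed or RNG stream.
#' @return list of class `synthetic_dataset` with `table` (binary
#'   [feature_table()]), `labels` (Control/Treatment), `truth` (perturbed
#'   feature ids), `truth_mask`, `applied_likelihoods`, `shuffled`.
#' @export
generate_dataset <- function(baseline_probs, spec = perturbation_spec(),
                             seed = 1L) {
  rng <- if (is.environment(seed)) seed else make_rng(seed)
  d <- length(baseline_probs)
  if (spec$n_perturbed > d) {
    stop("n_perturbed exceeds the number of baseline features")
  }
  if (is.null(names(baseline_probs))) {
    names(baseline_probs) <- paste0("ASV", seq_len(d))
  }
  feature_ids <- names(baseline_probs)
  n_c <- spec$n_control
  n_t <- spec$n_treatment

  perturbed <- sort(rng_sample_int(rng, d, spec$n_perturbed))
  p_n <- rng_sample(rng, spec$likelihood_choices, spec$n_perturbed,
                    replace = TRUE)
  q <- perturb_probability(baseline_probs[perturbed], p_n)

  draw_block <- function(n, probs) {
    m <- matrix(0L, n, d)
    for (j in seq_len(d)) m[, j] <- rng_rbinom(rng, n, 1L, probs[j])
    m
  }
  probs_t <- baseline_probs
  probs_t[perturbed] <- q
  control <- draw_block(n_c, baseline_probs)
  treatment <- draw_block(n_t, probs_t)
  values <- rbind(control, treatment)

  n_shuffle <- ceiling(spec$shuffle_fraction * d)
  shuffled <- integer(0)
  if (n_shuffle > 0) {
    shuffled <- sort(rng_sample_int(rng, d, n_shuffle))
    for (j in shuffled) {
      values[, j] <- rng_sample(rng, values[, j], nrow(values))
    }
  }
  sample_ids <- c(sprintf("Control_%02d", seq_len(n_c)),
                  sprintf("Treatment_%02d", seq_len(n_t)))
  labels <- stats::setNames(
    rep(c("Control", "Treatment"), c(n_c, n_t)), sample_ids)
  truth_mask <- stats::setNames(logical(d), feature_ids)
  truth_mask[perturbed] <- TRUE
  structure(
    list(table = feature_table(values, sample_ids, feature_ids),
         labels = labels,
         truth = feature_ids[perturbed],
         truth_mask = truth_mask,
         applied_likelihoods = stats::setNames(p_n, feature_ids[perturbed]),
         shuffled = feature_ids[shuffled],
         spec = spec),
    class = "synthetic_dataset"
  )
}

#' @export
#' @method print synthetic_dataset
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic_dataset: %d samples (%d control), %d features, %d perturbed, %d shuffled\n",
    nrow(x$table$values), x$spec$n_control, ncol(x$table$values),
    length(x$truth), length(x$shuffled)))
  invisible(x)
}
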