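test_that("baseline probability estimation is a clipped column mean", {
  m <- matrix(0L, 24, 3)
  m[1:12, 1] <- 1L           # 12/24 -> 0.5
  # column 2 all absent -> clipped to 1/48; column 3 all present -> 47/48
  m[, 3] <- 1L
  ft <- feature_table(m)
  p <- estimate_baseline_probs(ft)
  expect_equal(unname(p), c(0.5, 1 / 48, 47 / 48))

  bt <- small_binary_table(20, 30, seed = 2)
  p2 <- estimate_baseline_probs(bt)
  raw <- colMeans(bt$values)
  inner <- raw > 1 / 40 & raw < 1 - 1 / 40
  expect_equal(p2[inner], raw[inner])
})

test_that("log-odds perturbation closed form", {
  expect_equal(perturb_probability(0.5, 2), 2 / 3)
  expect_equal(perturb_probability(0.3, 1), 0.3)
  expect_equal(perturb_probability(0.2, 0.5), 1 / 9)
  expect_equal(perturb_probability(0.1, 8), 0.8 / 1.7)
  expect_error(perturb_probability(0, 2), "p_o")
  expect_error(perturb_probability(0.5, -1), "p_n")

  # monotonicity over a grid: q increases in p_n at fixed p_o and in p_o
  # at fixed p_n
  p_o <- seq(0.05, 0.95, length.out = 10)
  p_n <- c(0.1, 0.125, 0.25, 0.5, 2, 4, 8, 10)
  for (p in p_o) expect_true(all(diff(perturb_probability(p, sort(p_n))) > 0))
  for (pn in p_n) expect_true(all(diff(perturb_probability(p_o, pn)) > 0))
  # solving the log-odds relation directly reproduces q
  q <- perturb_probability(0.37, 4)
  expect_equal(log(q / (1 - q)), log(0.37 / 0.63) + log(4))
})

test_that("generated datasets honour the 48/24 design and ground truth", {
  probs <- generate_baseline(400, seed = 3)
  ds <- generate_dataset(probs, perturbation_spec(n_perturbed = 50), seed = 1)
  expect_equal(dim(ds$table), c(48L, 400L))
  expect_equal(sum(ds$labels == "Control"), 24L)
  expect_equal(length(ds$truth), 50L)
  expect_equal(sum(ds$truth_mask), 50L)
  expect_length(ds$shuffled, ceiling(0.05 * 400))
  expect_true(ds$table$is_binary)
  expect_true(all(ds$applied_likelihoods %in%
                    c(0.1, 0.125, 0.25, 0.5, 2, 4, 8, 10)))

  # determinism
  ds2 <- generate_dataset(probs, perturbation_spec(n_perturbed = 50), seed = 1)
  expect_identical(ds$table$values, ds2$table$values)
  expect_identical(ds$truth, ds2$truth)

  expect_error(generate_dataset(probs[1:20],
                                perturbation_spec(n_perturbed = 50), 1),
               "n_perturbed")
})

test_that("treatment frequencies track the perturbed probabilities", {
  # one strongly up-shifted feature, no shuffling, many treatment samples
  probs <- c(A = 0.1, B = 0.3, C = 0.5)
  spec <- perturbation_spec(n_perturbed = 1, likelihood_choices = 8,
                           shuffle_fraction = 0, n_control = 50,
                           n_treatment = 5000)
  ds <- generate_dataset(probs, spec, seed = 2)
  f_treat <- colMeans(ds$table$values[ds$labels == "Treatment", ])
  q <- perturb_probability(probs[ds$truth], 8)
  # binomial 99.9% CI at n = 5000
  expect_lt(abs(f_treat[ds$truth] - q), 3.3 * sqrt(q * (1 - q) / 5000))
  untouched <- setdiff(names(probs), ds$truth)
  for (f in untouched) {
    expect_lt(abs(f_treat[f] - probs[f]),
              3.3 * sqrt(probs[f] * (1 - probs[f]) / 5000) + 0.01)
  }
})

test_that("with shuffling off, group differences localize to truth features", {
  probs <- generate_baseline(120, seed = 9)
  spec <- perturbation_spec(n_perturbed = 20, likelihood_choices = c(0.1, 10),
                           shuffle_fraction = 0, n_control = 600,
                           n_treatment = 600)
  ds <- generate_dataset(probs, spec, seed = 5)
  ctl <- ds$table$values[ds$labels == "Control", ]
  trt <- ds$table$values[ds$labels == "Treatment", ]
  pvals <- vapply(seq_len(120), function(j) {
    suppressWarnings(stats::prop.test(c(sum(ctl[, j]), sum(trt[, j])),
                                      c(600, 600))$p.value)
  }, 0)
  sig <- which(pvals < 1e-4)
  # every strongly significant difference is a planted feature
  expect_true(all(colnames(ds$table$values)[sig] %in% ds$truth))
})

test_that("self-contained baselines follow the truncated sparsity profile", {
  p <- generate_baseline(1000, seed = 4)
  expect_length(p, 1000L)
  expect_true(all(p > 0 & p < 1))
  expect_true(all(p >= 2 / 24 - 1e-12))  # prevalence-filter floor
  expect_identical(p, generate_baseline(1000, seed = 4))
  # mean occupancy within Monte-Carlo range of the truncated-profile mean
  expect_gt(mean(p), 0.12)
  expect_lt(mean(p), 0.35)
})
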