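test_that("balanced accuracy follows the max-marginal confusion form", {
  cm <- matrix(c(10, 0, 0, 10), 2, 2)
  expect_equal(balanced_accuracy(cm), 1.0)
  expect_equal(balanced_accuracy(matrix(c(8, 2, 2, 8), 2, byrow = TRUE)), 0.8)
  expect_equal(balanced_accuracy(matrix(c(5, 5, 0, 10), 2, byrow = TRUE)),
               (5 / 10 + 10 / 15) / 2)

  # a constant predictor on balanced two-class data scores 0.25
  truth <- rep(c("A", "B"), each = 10)
  pred <- rep("A", 20)
  expect_equal(balanced_accuracy(confusion_matrix(truth, pred,
                                                  c("A", "B"))), 0.25)
  expect_error(balanced_accuracy(matrix(0, 2, 2)), "empty")
})

test_that("max-marginal form equals mean recall on symmetric margins", {
  # when every class has equal row and column sums, max(row, col) = row
  set.seed(41)
  for (i in 1:50) {
    off <- sample(0:5, 1)
    cm <- matrix(c(7, off, off, 9), 2, 2)
    expect_equal(balanced_accuracy(cm), balanced_accuracy_recall(cm))
  }
  # and differs in general
  cm <- matrix(c(5, 5, 0, 10), 2, byrow = TRUE)
  expect_gt(balanced_accuracy_recall(cm), balanced_accuracy(cm))
})

test_that("feature-recovery MCC matches closed form and conventions", {
  u <- paste0("F", 1:1000)
  truth <- u[1:25]
  expect_equal(mcc_feature_recovery(truth, truth, u), 1.0)

  # TP=20 FP=5 FN=5 TN=970
  sel <- c(u[1:20], u[101:105])
  expect_equal(mcc_feature_recovery(sel, truth, u),
               (20 * 970 - 5 * 5) / sqrt(25 * 25 * 975 * 975))

  # disjoint selection with TN > 0 is negative
  expect_lt(mcc_feature_recovery(u[26:50], truth, u), 0)

  # zero-denominator convention: selecting everything
  expect_equal(mcc_feature_recovery(u, truth, u), 0)

  # symmetry under swapping selected and truth
  set.seed(5)
  for (i in 1:20) {
    a <- sample(u, 30)
    b <- sample(u, 30)
    expect_equal(mcc_feature_recovery(a, b, u), mcc_feature_recovery(b, a, u))
  }
})

test_that("Cohen's kappa anchors and null behaviour", {
  expect_equal(cohen_kappa(c("A", "A", "B"), c("A", "A", "B")), 1.0)
  expect_equal(cohen_kappa(c("A", "A", "B", "B"), c("B", "B", "A", "A")), -1.0)
  # both raters constant and identical: p_e = 1, agreement perfect
  expect_equal(cohen_kappa(rep("A", 4), rep("A", 4)), 1.0)

  # independent labelings average near zero
  set.seed(11)
  ks <- replicate(1000, cohen_kappa(sample(c("A", "B"), 20, TRUE),
                                    sample(c("A", "B"), 20, TRUE)))
  expect_lt(abs(mean(ks)), 0.03)
})

test_that("Spearman consistency uses average ranks and flags constants", {
  expect_equal(spearman_rank_consistency(1:10, 1:10), 1.0)
  expect_equal(spearman_rank_consistency(1:10, 10:1), -1.0)
  a <- c(1, 2, 2, 3, 0, 0)
  b <- c(2, 1, 3, 5, 1, 0)
  expect_equal(spearman_rank_consistency(a, b),
               stats::cor(rank(a), rank(b)))  # rank-then-Pearson definition
  expect_warning(r <- spearman_rank_consistency(rep(1, 5), 1:5), "constant")
  expect_true(is.na(r))
})

test_that("Jaccard distance arithmetic", {
  expect_equal(jaccard_distance(1:5, 1:5), 0)
  expect_equal(jaccard_distance(1:3, 4:6), 1)
  expect_equal(jaccard_distance(1:100, 51:150), 2 / 3)
  expect_equal(jaccard_distance(character(0), character(0)), 0)
})

test_that("metrics stay within their stated bounds on random inputs", {
  set.seed(21)
  for (i in 1:200) {
    cm <- matrix(rpois(4, 5), 2, 2)
    if (sum(cm) == 0) next
    expect_true(balanced_accuracy(cm) >= 0 && balanced_accuracy(cm) <= 1)
    a <- sample(letters[1:3], 15, TRUE)
    b <- sample(letters[1:3], 15, TRUE)
    k <- cohen_kappa(a, b)
    expect_true(k >= -1 && k <= 1)
    sel <- sample(50, sample(49, 1))
    tru <- sample(50, sample(49, 1))
    m <- mcc_feature_recovery(sel, tru, 50)
    expect_true(m >= -1 && m <= 1)
  }
})
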