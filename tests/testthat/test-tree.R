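test_that("entropy closed forms", {
  expect_equal(entropy(c("A", "A", "B", "B")), 1.0)
  expect_equal(entropy(rep("A", 4)), 0.0)
  expect_equal(entropy(c("A", "A", "A", "B")),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)))
  expect_error(entropy(character(0)), "empty")
})

test_that("information gain closed forms and bounds", {
  y <- c("A", "A", "B", "B")
  expect_equal(information_gain(y, c("l", "l", "r", "r")), 1.0)
  expect_equal(information_gain(y, rep("l", 4)), 0.0)
  # [A,A,B],[B]
  expect_equal(information_gain(y, c("l", "l", "l", "r")),
               1 - 0.75 * entropy(c("A", "A", "B")))
  # property: gain in [0, H(parent)] for random partitions
  set.seed(12)
  for (i in 1:100) {
    yy <- sample(c("A", "B", "C"), 12, TRUE)
    if (length(unique(yy)) < 2) next
    part <- sample(c("l", "r"), 12, TRUE)
    g <- information_gain(yy, part)
    expect_true(g >= -1e-12 && g <= entropy(yy) + 1e-12)
  }
})

test_that("oracle hyperplane geometry and tie rule", {
  X <- rbind(c(0, 0), c(2, 0), c(3, 0), c(1, 5))
  found <- FALSE
  for (s in 1:25) {
    o <- draw_oracle(X[1:2, ], rng = s)
    # anchors (0,0) and (2,0) in some order
    expect_equal(o$midpoint, c(1, 0))
    expect_true(all(o$normal == c(2, 0)) || all(o$normal == c(-2, 0)))
    side <- landmark:::oracle_side(o, X)
    # the two anchors always fall on opposite sides
    expect_false(side[1] == side[2])
    if (all(o$normal == c(2, 0))) {
      found <- TRUE
      expect_equal(side[3], "right")   # positive side of the normal
      expect_equal(side[4], "right")   # exactly on the hyperplane -> positive
    }
  }
  expect_true(found)
  # all rows identical: oracle unavailable
  expect_null(draw_oracle(rbind(c(1, 1), c(1, 1), c(1, 1)), rng = 1))
})

test_that("choose_split picks the best and randomizes exact ties", {
  mk <- function(gain, tag) {
    s <- landmark:::new_splitter("logistic_l2", matrix(1), 0, c("A", "B"), 1L)
    s$achieved_gain <- gain
    s$tag <- tag
    s
  }
  # clear winner is always chosen
  for (s in 1:20) {
    expect_equal(choose_split(list(mk(0.8, 1), mk(0.3, 2)), rng = s)$tag, 1)
  }
  # exact ties split ~50/50 over seeded draws (binomial 99.9% band)
  picks <- vapply(1:1000, function(s) {
    choose_split(list(mk(0.8, 1), mk(0.8, 2)), rng = s)$tag
  }, 0)
  expect_gt(mean(picks == 1), 0.44)
  expect_lt(mean(picks == 1), 0.56)
  # nothing above the gain threshold: leaf signal
  expect_null(choose_split(list(mk(0, 1), mk(0, 2)), rng = 1))
})

test_that("trees grow to purity on separable data and stay leaves on XOR", {
  b <- make_blobs(n = 20, sd = 0.4, seed = 21)
  tr <- build_tree(b$x, b$y, fast_control(), seed = 2)
  P <- predict_tree(tr, b$x)
  expect_equal(colnames(P), c("A", "B"))
  expect_equal(unname(P[cbind(seq_along(b$y), match(b$y, colnames(P)))]),
               rep(1, 40))

  # pure input: single leaf
  tr2 <- build_tree(b$x, rep("A", 40), fast_control(), seed = 1,
                    classes = c("A", "B"))
  expect_null(tr2$root$splitter)

  # 4-point XOR with linear candidates only and no oracle: no positive-gain
  # split exists, the root stays a leaf
  X <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  y <- c("A", "A", "B", "B")
  tr3 <- build_tree(X, y, landmark_control(oracle = FALSE, use_nnet = FALSE,
                                           use_node_bootstrap = FALSE),
                    seed = 5)
  expect_null(tr3$root$splitter)
  expect_equal(unname(predict_tree(tr3, X)[1, ]), c(0.5, 0.5))
})

test_that("prediction routes to leaves and rows sum to one", {
  ds <- small_synth(seed = 3)
  X <- ds$table$values
  tr <- build_tree(X, ds$labels, fast_control(), seed = 7)
  P <- predict_tree(tr, X)
  expect_equal(unname(rowSums(P)), rep(1, nrow(X)))
  # dimension mismatch errors
  expect_error(predict_tree(tr, X[, 1:10]), "mismatch")

  ids <- apply_tree(tr, X)
  expect_true(all(ids %in% landmark:::tree_leaf_ids(tr)))
  # identical samples land in identical leaves
  X2 <- rbind(X[1, ], X[1, ])
  expect_equal(length(unique(apply_tree(tr, X2))), 1L)
  # a single-leaf tree sends everything to the root
  tr2 <- build_tree(X, rep("T", nrow(X)), fast_control(), seed = 1,
                    classes = c("C", "T"))
  expect_equal(unique(apply_tree(tr2, X)), tr2$root$id)
})

test_that("tree construction is reproducible end-to-end", {
  ds <- small_synth(seed = 4)
  a <- build_tree(ds$table$values, ds$labels, fast_control(), seed = 31)
  b <- build_tree(ds$table$values, ds$labels, fast_control(), seed = 31)
  expect_equal(apply_tree(a, ds$table$values), apply_tree(b, ds$table$values))
  expect_equal(predict_tree(a, ds$table$values),
               predict_tree(b, ds$table$values))
})

test_that("single splitter trees beat single axis-aligned trees on spirals", {
  # mean over seeds of test accuracy: one multivariate-splitter tree vs one
  # CART tree on the same two-spiral draws
  lm_scores <- c()
  cart_scores <- c()
  for (s in 1:10) {
    sp <- make_two_spirals(n = 60, noise = 0.1, turns = 1.5, seed = s)
    idx <- stratified_splits(sp$y, 0.2, 1, seed_offset = s * 100)$repeats[[1]]
    tr <- build_tree(sp$x[idx$train, ], sp$y[idx$train],
                     landmark_control(use_nnet = FALSE), seed = s)
    P <- predict_tree(tr, sp$x[idx$test, ])
    pred <- colnames(P)[max.col(P, ties.method = "first")]
    lm_scores <- c(lm_scores, mean(pred == sp$y[idx$test]))
    df <- data.frame(y = factor(sp$y[idx$train]), sp$x[idx$train, ])
    ct <- rpart::rpart(y ~ ., df, method = "class")
    cp <- as.character(predict(ct, data.frame(sp$x[idx$test, ]),
                               type = "class"))
    cart_scores <- c(cart_scores, mean(cp == sp$y[idx$test]))
  }
  expect_gt(mean(lm_scores), mean(cart_scores))
})

test_that("bounded gain at near-pure nodes", {
  # when one class holds >= 95% of samples the achievable gain cannot
  # exceed the node entropy
  set.seed(33)
  X <- matrix(rnorm(80), 40, 2)
  y <- c(rep("A", 38), "B", "B")
  h <- entropy(y)
  for (fam in c("logistic_l2", "linear_svc")) {
    sp <- fit_linear_splitter(fam, X, y, rng = 2L)
    if (is.null(sp)) next
    expect_lte(information_gain(y, predict_splitter(sp, X)), h + 1e-12)
  }
})
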