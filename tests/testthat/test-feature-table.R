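test_that("feature tables validate identifiers and values", {
  m <- matrix(1:6, 2, 3)
  ft <- feature_table(m, c("a", "b"), c("x", "y", "z"))
  expect_equal(dim(ft), c(2L, 3L))
  expect_false(ft$is_binary)

  expect_error(feature_table(m, c("a", "a"), c("x", "y", "z")),
               "duplicate sample")
  expect_error(feature_table(m, c("a", "b"), c("x", "x", "z")),
               "duplicate feature")
  m2 <- m; m2[1, 2] <- -1
  expect_error(feature_table(m2, c("a", "b"), c("x", "y", "z")), "negative")
})

test_that("TSV round-trip is lossless and errors are located", {
  ft <- small_binary_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(ft, path)
  back <- read_feature_table(path, "tsv")
  expect_equal(back$values, ft$values)
  expect_equal(back$sample_ids, ft$sample_ids)
  expect_equal(back$feature_ids, ft$feature_ids)

  # counts preserved exactly and transposed reading works
  ct <- toy_count_table()
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(ct, p2)
  tr <- read_feature_table(p2, "tsv")
  expect_identical(unname(tr$values), unname(ct$values))  # exact doubles

  # transposed file (features as rows)
  p3 <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(feature_id = ct$feature_ids, t(ct$values),
                   check.names = FALSE)
  utils::write.table(df, p3, sep = "\t", quote = FALSE, row.names = FALSE)
  tt <- read_feature_table(p3, "tsv", transpose = TRUE)
  expect_equal(unname(tt$values), unname(ct$values))

  # degenerate and malformed files
  p4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("sample_id\tF1", p4)
  expect_error(read_feature_table(p4, "tsv"), "no samples")
  p5 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tF1\tF2", "S1\t1\toops"), p5)
  expect_error(read_feature_table(p5, "tsv"), "non-numeric")
})

test_that("BIOM tables read back with samples as rows", {
  ct <- toy_count_table()
  b <- biomformat::make_biom(t(ct$values))
  path <- withr::local_tempfile(fileext = ".biom")
  biomformat::write_biom(b, path)
  ft <- read_feature_table(path, "biom")
  expect_equal(unname(ft$values), unname(ct$values))
})

test_that("label files round-trip and align to sample order", {
  labels <- c(S1 = "river", S2 = "delta", S3 = "river")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_labels(labels, path)
  back <- read_labels(path, sample_ids = c("S3", "S1", "S2"))
  expect_equal(back, labels[c("S3", "S1", "S2")])
  expect_error(read_labels(path, sample_ids = c("S1", "S9")), "S9")
})

test_that("presence-absence transform binarizes and is idempotent", {
  ct <- toy_count_table()
  pa <- to_presence_absence(ct)
  expect_equal(unname(pa$values),
               matrix(c(0, 1, 1, 0, 1, 1), nrow = 3, byrow = TRUE))
  expect_true(pa$is_binary)
  expect_equal(to_presence_absence(pa)$values, pa$values)

  # all-zero column stays all-zero
  m <- cbind(A = c(0, 0), B = c(2, 1))
  rownames(m) <- c("s1", "s2")
  expect_equal(unname(to_presence_absence(feature_table(m))$values[, 1]),
               c(0, 0))
})

test_that("prevalence filter keeps features in >= min_samples samples", {
  m <- rbind(c(1, 1, 0, 1), c(0, 1, 0, 1), c(0, 1, 0, 0), c(0, 0, 0, 1))
  dimnames(m) <- list(paste0("S", 1:4), paste0("F", 1:4))
  ft <- feature_table(m)
  kept <- filter_min_prevalence(ft, 2)
  expect_equal(kept$feature_ids, c("F2", "F4"))  # singleton F1, empty F3 drop

  expect_equal(filter_min_prevalence(ft, 0)$values, ft$values)
  expect_error(filter_min_prevalence(ft, 5), "reduce the threshold")
  expect_error(filter_min_prevalence(toy_count_table()), "presence-absence")

  # brute-force oracle on a random table
  bt <- small_binary_table(20, 50, seed = 3)
  expect_equal(filter_min_prevalence(bt, 4)$feature_ids,
               bt$feature_ids[colSums(bt$values) >= 4])
})

test_that("stratified splits respect proportions and iteration-number seeds", {
  labels <- rep(c("A", "B"), each = 5)
  sched <- stratified_splits(labels, 0.2, 30)
  expect_length(sched$repeats, 30L)
  for (r in sched$repeats[1:5]) {
    expect_length(r$train, 8L)
    expect_length(r$test, 2L)
    expect_setequal(c(r$train, r$test), 1:10)
    expect_equal(sort(unique(labels[r$test])), c("A", "B"))
  }
  expect_equal(vapply(sched$repeats, `[[`, 0, "seed"), as.numeric(1:30))

  # determinism: regenerating the schedule reproduces it bit-exactly
  again <- stratified_splits(labels, 0.2, 30)
  expect_identical(sched$repeats, again$repeats)

  # 48 samples split in half: 12 per class on each side
  labels48 <- rep(c("A", "B"), each = 24)
  half <- stratified_splits(labels48, 0.5, 3)
  for (r in half$repeats) {
    expect_length(r$test, 24L)
    expect_equal(as.integer(table(labels48[r$test])), c(12L, 12L))
    expect_equal(as.integer(table(labels48[r$train])), c(12L, 12L))
  }

  expect_error(stratified_splits(c("A", "A", "B"), 0.2, 2), "B")
})
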