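#' Construct a feature table
#'
#' A feature table is the package's universal data carrier: a numeric matrix
#' of non-negative counts (or 0/1 presences) with samples as rows and
#' features (typically amplicon sequence variants, ASVs) as columns.
#'
#' @param values numeric matrix, rows = samples, columns = features.
#' @param sample_ids character vector of unique sample identifiers. Defaults
#'   to the matrix row names.
#' @param feature_ids character vector of unique feature identifiers.
#'   Defaults to the matrix column names.
#'
#' @return An object of class `feature_table` with elements `values`,
#'   `sample_ids`, `feature_ids` and `is_binary`.
#' @export
feature_table <- function(values, sample_ids = rownames(values),
                          feature_ids = colnames(values)) {
  values <- as.matrix(values)
  if (nrow(values) == 0L) stop("no samples in feature table")
  if (ncol(values) == 0L) stop("no features in feature table")
  if (!is.numeric(values)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(values), nrow(values)))) &
                   !is.na(values), arr.ind = TRUE)
    if (nrow(bad) > 0L) {
      stop(sprintf("non-numeric cell at row %d, column %d", bad[1, 1], bad[1, 2]))
    }
    storage.mode(values) <- "double"
  }
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)
    stop(sprintf("non-numeric or missing cell at row %d, column %d",
                 bad[1, 1], bad[1, 2]))
  }
  if (any(values < 0)) stop("feature table contains negative values")
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (is.null(feature_ids)) feature_ids <- paste0("F", seq_len(ncol(values)))
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (length(sample_ids) != nrow(values)) {
    stop("length of sample_ids does not match number of rows")
  }
  if (length(feature_ids) != ncol(values)) {
    stop("length of feature_ids does not match number of columns")
  }
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup) > 0L) {
    stop("duplicate sample identifiers: ", paste(unique(dup), collapse = ", "))
  }
  dup <- feature_ids[duplicated(feature_ids)]
  if (length(dup) > 0L) {
    stop("duplicate feature identifiers: ", paste(unique(dup), collapse = ", "))
  }
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(
    list(values = values, sample_ids = sample_ids, feature_ids = feature_ids,
         is_binary = all(values %in% c(0, 1))),
    class = "feature_table"
  )
}

#' @export
#' @method print feature_table
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d features (%s)\n",
              length(x$sample_ids), length(x$feature_ids),
              if (x$is_binary) "presence-absence" else "counts"))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Read a feature table from disk
#'
#' Reads a delimited sample-by-feature table (header row of feature
#' identifiers, first column of sample identifiers) or a BIOM file.
#' Amplicon tables often ship transposed (features as rows); set
#' `transpose = TRUE` to accept those.
#'
#' @param path file path.
#' @param format one of `"tsv"`, `"csv"`, `"biom"`. BIOM support is
#'   read-only and requires the `biomformat` package.
#' @param transpose logical; if `TRUE` the file stores features as rows.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, format = c("tsv", "csv", "biom"),
                               transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("reading BIOM files requires the 'biomformat' package")
    }
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))
    # BIOM stores observations (features) as rows
    return(feature_table(t(m)))
  }
  sep <- if (format == "tsv") "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                          check.names = FALSE, comment.char = "",
                          quote = "\"", stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no samples in ", path)
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df, 2, as.numeric))) & !is.na(df),
                 arr.ind = TRUE)
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric cell at row %d, column %d of %s",
                   bad[1, 1], bad[1, 2], path))
    }
    storage.mode(m) <- "double"
  }
  if (transpose) m <- t(m)
  feature_table(m)
}

#' Write a feature table as TSV
#'
#' @param table a [feature_table()].
#' @param path output path; a header row of feature ids and a first column
#'   (`sample_id`) of sample ids are written.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(sample_id = table$sample_ids, table$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column sample label file
#'
#' @param path TSV with columns `sample_id` and `class` (header optional by
#'   position).
#' @param sample_ids optional sample ordering to align labels to.
#' @return named character vector of class labels.
#' @export
read_labels <- function(path, sample_ids = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("label file must have two columns (sample_id, class)")
  labels <- stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, names(labels))
    if (length(missing) > 0L) {
      stop("labels missing for samples: ", paste(missing, collapse = ", "))
    }
    labels <- labels[sample_ids]
  }
  labels
}

#' Write sample labels as two-column TSV
#'
#' @param labels named character vector (names = sample ids) or unnamed
#'   vector with `sample_ids` supplied.
#' @param path output path.
#' @param sample_ids sample ids when `labels` is unnamed.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path, sample_ids = names(labels)) {
  df <- data.frame(sample_id = sample_ids, class = as.character(labels))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Presence-absence transform
#'
#' Binarizes a count table: an entry becomes 1 exactly when the source count
#' is greater than zero. This is the normalization used for sparse,
#' compositional amplicon data in place of rarefaction or log-ratio
#' transforms.
#'
#' @param table a [feature_table()] of counts.
#' @return a binary [feature_table()].
#' @export
to_presence_absence <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (any(table$values < 0)) stop("negative values in count table")
  v <- (table$values > 0) * 1
  feature_table(v, table$sample_ids, table$feature_ids)
}

#' Prevalence filter
#'
#' Retains features observed in at least `min_samples` samples. The default
#' of 2 drops singleton features, keeping only ASVs shared between samples.
#'
#' @param table a binary [feature_table()].
#' @param min_samples minimum number of samples a feature must occur in.
#' @return filtered [feature_table()]; feature order preserved.
#' @export
filter_min_prevalence <- function(table, min_samples = 2L) {
  stopifnot(inherits(table, "feature_table"))
  if (!table$is_binary) {
    stop("prevalence filter expects a presence-absence table; ",
         "apply to_presence_absence() first")
  }
  keep <- colSums(table$values) >= min_samples
  if (!any(keep)) {
    stop("all features removed at min_samples = ", min_samples,
         "; reduce the threshold")
  }
  feature_table(table$values[, keep, drop = FALSE], table$sample_ids,
                table$feature_ids[keep])
}

#' Seeded stratified train/test split schedule
#'
#' Produces `n_repeats` stratified train/test splits. For reproducibility
#' the random state of repeat `i` is the iteration number itself (offset by
#' `seed_offset`), so schedules are reconstructible from the repeat index
#' alone. Test slots are allocated per class by the largest-remainder
#' convention: each class contributes `floor(test_fraction * n_class)`
#' samples and leftover slots go to the classes with the largest fractional
#' remainders.
#'
#' @param labels class label per sample (character or factor).
#' @param test_fraction fraction of samples assigned to the test set.
#' @param n_repeats number of repeats (30 in the standard harness).
#' @param seed_offset integer added to the iteration number to form each
#'   repeat's seed.
#' @return object of class `split_schedule`: a list of repeats, each with
#'   `train`, `test` (integer indices) and `seed`.
#' @export
stratified_splits <- function(labels, test_fraction = 0.2, n_repeats = 30L,
                              seed_offset = 0L) {
  labels <- as.character(labels)
  n <- length(labels)
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must be in (0, 1)")
  }
  tab <- table(labels)
  too_small <- names(tab)[tab < 2L]
  if (length(too_small) > 0L) {
    stop("class too small to stratify: ", paste(too_small, collapse = ", "))
  }
  n_test_total <- round(test_fraction * n)
  if (n_test_total < 1L || n_test_total >= n) {
    stop("test_fraction leaves an empty train or test set")
  }
  classes <- names(tab)
  base <- floor(test_fraction * as.integer(tab))
  rem <- test_fraction * as.integer(tab) - base
  shortfall <- n_test_total - sum(base)
  counts <- base
  if (shortfall > 0L) {
    extra <- order(rem, decreasing = TRUE)[seq_len(shortfall)]
    counts[extra] <- counts[extra] + 1L
  } else if (shortfall < 0L) {
    drop <- order(rem, decreasing = FALSE)
    drop <- drop[counts[drop] > 0L][seq_len(-shortfall)]
    counts[drop] <- counts[drop] - 1L
  }
  # every class must keep at least one training sample
  counts <- pmin(counts, as.integer(tab) - 1L)
  repeats <- lapply(seq_len(n_repeats), function(i) {
    seed <- seed_offset + i
    rng <- make_rng(seed)
    test_idx <- integer(0)
    for (k in seq_along(classes)) {
      idx <- which(labels == classes[k])
      if (counts[k] > 0L) {
        test_idx <- c(test_idx, rng_sample(rng, idx, counts[k]))
      }
    }
    test_idx <- sort(test_idx)
    list(train = setdiff(seq_len(n), test_idx), test = test_idx, seed = seed)
  })
  structure(list(repeats = repeats, labels = labels,
                 test_fraction = test_fraction),
            class = "split_schedule")
}

#' @export
#' @method print split_schedule
print.split_schedule <- function(x, ...) {
  cat(sprintf("split_schedule: %d repeats, test fraction %.2f (%d/%d)\n",
              length(x$repeats), x$test_fraction,
              length(x$repeats[[1]]$train), length(x$repeats[[1]]$test)))
  invisible(x)
}
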