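# Cross-validation harness: fold assignment, MAE, aggregate
# statistics, and prediction export.

test_that("fold assignment partitions the samples with balanced sizes", {
  fa <- assign_folds(12, 6, seed = 1)
  sizes <- tabulate(fa$fold_of + 1, nbins = 6)
  expect_equal(sizes, rep(2, 6))

  fa13 <- assign_folds(13, 6, seed = 1)
  s13 <- sort(tabulate(fa13$fold_of + 1, nbins = 6), decreasing = TRUE)
  expect_equal(s13, c(3, 2, 2, 2, 2, 2))
  expect_equal(length(fa13$fold_of), 13)

  expect_identical(assign_folds(40, 6, seed = 9), assign_folds(40, 6, seed = 9))
  expect_error(assign_folds(4, 6), "at least k")
  expect_error(assign_folds(10, 1), ">= 2")
})

test_that("mean absolute error matches hand arithmetic and the elementwise oracle", {
  expect_equal(mean_absolute_error(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mean_absolute_error(c(0, 0), c(1, 3)), 2)
  expect_error(mean_absolute_error(1:3, 1:4), "length mismatch")
  withr::with_seed(2, {
    a <- rnorm(200); b <- rnorm(200)
  })
  oracle <- sum(vapply(seq_along(a), function(i) abs(a[i] - b[i]),
                       numeric(1))) / length(a)
  expect_equal(mean_absolute_error(a, b), oracle, tolerance = 1e-12)
  perm <- withr::with_seed(3, sample.int(200))
  expect_equal(mean_absolute_error(a[perm], b[perm]),
               mean_absolute_error(a, b))
})

test_that("an oracle regressor scores a zero MAE with a degenerate interval", {
  x <- withr::with_seed(4, matrix(rnorm(60 * 3), 60))
  y <- withr::with_seed(5, sample(1:12, 60, replace = TRUE))
  # factory receives training labels; returns the hold-out truth by
  # memorizing the full label vector through row signatures
  sig <- apply(round(x, 10), 1, paste, collapse = ",")
  lookup <- stats::setNames(y, sig)
  oracle_factory <- function(xt, yt) function(xv)
    unname(lookup[apply(round(xv, 10), 1, paste, collapse = ",")])
  res <- cross_validate(x, y, oracle_factory, k = 6, seed = 1)
  expect_equal(res$mean_mae, 0)
  expect_equal(res$standard_error, 0)
  expect_equal(c(res$ci95_low, res$ci95_high), c(0, 0))
})

test_that("constant-shift predictors give zero-variance fold MAEs", {
  x <- matrix(seq_len(36), ncol = 1)
  y <- rep(4, 36)
  shift_factory <- function(xt, yt) function(xv) rep(5, nrow(xv))
  res <- cross_validate(x, y, shift_factory, k = 6, seed = 2)
  expect_equal(res$fold_maes, rep(1, 6))
  expect_equal(res$mean_mae, 1)
  expect_equal(res$standard_error, 0)
})

test_that("aggregate statistics follow the fold-level definitions", {
  x <- matrix(rnorm(60), ncol = 1)
  y <- withr::with_seed(6, runif(60, 1, 12))
  mean_factory <- function(xt, yt) function(xv) rep(mean(yt), nrow(xv))
  res <- cross_validate(x, y, mean_factory, k = 6, seed = 3)
  expect_equal(res$mean_mae, mean(res$fold_maes))
  expect_equal(res$standard_error, sd(res$fold_maes) / sqrt(6))
  expect_equal(res$ci95_low, res$mean_mae - 1.96 * res$standard_error)
  expect_equal(res$ci95_high, res$mean_mae + 1.96 * res$standard_error)
  # worked example for the spread statistics: fold MAEs 0..5
  fm <- 0:5
  expect_equal(sd(fm) / sqrt(6), 0.7637626, tolerance = 1e-6)
})

test_that("every sample is predicted exactly once and folds never leak", {
  x <- matrix(rnorm(45), ncol = 1)
  y <- rnorm(45)
  seen_train <- list()
  factory <- function(xt, yt) {
    seen_train[[length(seen_train) + 1]] <<- xt[, 1]
    function(xv) rep(0, nrow(xv))
  }
  res <- cross_validate(x, y, factory, k = 6, seed = 4,
                        sample_ids = sprintf("s%02d", 1:45))
  expect_equal(sort(res$predictions$sample_id), sort(sprintf("s%02d", 1:45)))
  expect_equal(nrow(res$predictions), 45)
  for (f in seq_along(seen_train)) {
    val_ids <- res$predictions$sample_id[res$predictions$fold == f - 1]
    val_x <- x[match(val_ids, sprintf("s%02d", 1:45)), 1]
    expect_length(intersect(val_x, seen_train[[f]]), 0)
  }
})

test_that("factory failures propagate with the fold index", {
  x <- matrix(1:12, ncol = 1)
  bad <- function(xt, yt) stop("boom")
  expect_error(cross_validate(x, 1:12, bad, k = 6), "fold 0")
})

test_that("prediction tables export and round-trip", {
  x <- matrix(rnorm(36), ncol = 1)
  y <- withr::with_seed(7, sample(1:9, 36, replace = TRUE))
  factory <- function(xt, yt) function(xv) rep(mean(yt), nrow(xv))
  res <- cross_validate(x, y, factory, k = 6, seed = 5, method = "demo")
  path <- withr::local_tempfile(fileext = ".csv")
  export_predictions(res, path)
  back <- read.csv(path, stringsAsFactors = FALSE)
  expect_equal(nrow(back), 36)
  expect_equal(back$measured, res$predictions$measured)
  expect_equal(back$estimated, res$predictions$estimated)
  expect_equal(back$fold, res$predictions$fold)
  plot_path <- withr::local_tempfile(fileext = ".png")
  export_predictions(res, path, plot_path)
  expect_true(file.exists(plot_path))
})
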