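# Six-fold cross-validated evaluation: per-fold mean absolute error,
# their mean, standard error (n-1 sd across folds / sqrt(k)) and the
# normal 95% confidence interval, plus export of the
# measured-vs-estimated prediction table.

#' Assign samples to cross-validation folds
#'
#' A seeded random permutation is dealt round-robin into k folds, so
#' fold sizes differ by at most one and the folds partition the
#' samples.
#'
#' @param n number of samples.
#' @param k number of folds (default 6).
#' @param seed permutation seed.
#' @return A list of class `fold_assignment` with `fold_of`, a length-n
#'   integer vector of 0-based fold indices.
#' @export
assign_folds <- function(n, k = 6L, seed = 0L) {
  n <- as.integer(n); k <- as.integer(k)
  if (k < 2) stop("k must be >= 2")
  if (n < k) stop("need at least k samples")
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  fold_of <- integer(n)
  fold_of[perm] <- rep_len(0:(k - 1), n)
  structure(list(n_samples = n, k = k, seed = as.integer(seed),
                 fold_of = fold_of),
            class = "fold_assignment")
}

#' Mean absolute error
#'
#' @param estimated,measured equal-length numeric vectors.
#' @return `mean(abs(estimated - measured))`.
#' @export
mean_absolute_error <- function(estimated, measured) {
  if (length(estimated) != length(measured)) stop("length mismatch")
  if (length(estimated) == 0) stop("empty vectors")
  mean(abs(estimated - measured))
}

#' k-fold cross-validation of a tiller regressor
#'
#' The factory receives only training-fold data (any standardization
#' must happen inside it) and returns a prediction function; the
#' held-out fold is predicted exactly once per sample.
#'
#' @param x n x d feature matrix or a data frame of covariates.
#' @param labels measured tiller counts, length n.
#' @param regressor_factory `function(train_x, train_y)` returning a
#'   `function(newdata)` that yields numeric estimates.
#' @param k number of folds (default 6).
#' @param seed fold-assignment seed.
#' @param sample_ids optional identifiers for the prediction table.
#' @param method label stored in the prediction records.
#' @return A list of class `cv_result` with `fold_maes`, `mean_mae`,
#'   `standard_error`, `ci95_low`, `ci95_high` and a `predictions`
#'   data frame (`sample_id`, `measured`, `estimated`, `fold`,
#'   `method`).
#' @export
cross_validate <- function(x, labels, regressor_factory, k = 6L, seed = 0L,
                           sample_ids = NULL, method = "regressor") {
  n <- if (is.data.frame(x) || is.matrix(x)) nrow(x) else length(x)
  if (n != length(labels)) stop("x and labels differ in length")
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(n))
  fa <- assign_folds(n, k, seed)
  take <- function(obj, idx)
    if (is.data.frame(obj) || is.matrix(obj)) obj[idx, , drop = FALSE] else obj[idx]
  fold_maes <- numeric(k)
  preds <- vector("list", k)
  for (f in 0:(k - 1)) {
    val <- which(fa$fold_of == f)
    trn <- which(fa$fold_of != f)
    predictor <- tryCatch(
      regressor_factory(take(x, trn), labels[trn]),
      error = function(e) stop(sprintf("regressor factory failed on fold %d: %s",
                                       f, conditionMessage(e)), call. = FALSE))
    est <- as.numeric(predictor(take(x, val)))
    fold_maes[f + 1] <- mean_absolute_error(est, labels[val])
    preds[[f + 1]] <- data.frame(sample_id = sample_ids[val],
                                 measured = labels[val], estimated = est,
                                 fold = f, method = method)
  }
  mean_mae <- mean(fold_maes)
  se <- sd(fold_maes) / sqrt(k)
  structure(list(fold_maes = fold_maes, mean_mae = mean_mae,
                 standard_error = se,
                 ci95_low = mean_mae - 1.96 * se,
                 ci95_high = mean_mae + 1.96 * se,
                 k = k, seed = as.integer(seed),
                 predictions = do.call(rbind, preds)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold: MAE %.4f (SE %.4f, 95%% CI [%.4f, %.4f])\n",
              x$k, x$mean_mae, x$standard_error, x$ci95_low, x$ci95_high))
  invisible(x)
}

#' Export the measured-vs-estimated prediction table
#'
#' Writes one CSV row per prediction record; optionally renders the
#' scatter plot with the identity diagonal (measured = estimated).
#'
#' @param result a [cross_validate()] result.
#' @param path CSV output path.
#' @param plot_path optional PNG path for the scatter plot.
#' @return Invisibly, the prediction data frame.
#' @export
export_predictions <- function(result, path, plot_path = NULL) {
  if (is.null(result$predictions) || nrow(result$predictions) == 0)
    stop("result has no predictions")
  write.csv(result$predictions, path, row.names = FALSE)
  if (!is.null(plot_path)) {
    grDevices::png(plot_path, width = 600, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::plot(result$predictions$measured, result$predictions$estimated,
                   col = "red", pch = 16,
                   xlab = "measured tiller number",
                   ylab = "estimated tiller number")
    graphics::abline(0, 1, col = "black")
  }
  invisible(result$predictions)
}
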