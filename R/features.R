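# Feature extraction from the headless backbone and tiller-count
# regression: epsilon-insensitive SVR with an RBF kernel (C = 100,
# epsilon = 1.0 by default) or a linear head trained with the backbone
# frozen.  Estimates are kept continuous (unrounded).

#' Extract features from a headless backbone
#'
#' Deterministic evaluation-mode forward pass that stops before the
#' task head; for the full-size architecture this is the second 4096-d
#' fully connected activation, for the tiny architecture the
#' `feature_width`-d fully connected activation.
#'
#' @param backbone a `tiller_backbone`.
#' @param images a single normalized image or a list of them, each at
#'   the backbone's expected input size.
#' @return An n x feature_dim numeric matrix; row names are sample
#'   ids, and the backbone provenance is attached as an attribute.
#' @export
extract_features <- function(backbone, images) {
  if (!inherits(backbone, "tiller_backbone")) stop("backbone must be a tiller_backbone")
  X <- images_to_matrix(images, backbone$arch)
  f <- cpp_cnn_forward(backbone$arch, backbone$weights, X, TRUE)
  out <- t(f)
  ids <- if (is.list(images) && !is.null(names(images))) names(images)
         else as.character(seq_len(nrow(out)))
  rownames(out) <- ids
  if (any(!is.finite(out))) stop("non-finite feature values")
  attr(out, "backbone_provenance") <- backbone$provenance
  out
}

#' SVR configuration
#'
#' @param kernel kernel name (default `"radial"`, the RBF kernel).
#' @param C cost parameter (default 100).
#' @param epsilon width of the insensitive tube (default 1.0).
#' @param kernel_width_rule `"scale"` (gamma = 1 / (feature_dim *
#'   variance of the feature entries)) or `"dim"` (1 / feature_dim).
#' @param standardize z-score the features before fitting (off by
#'   default; the scaling is stored and re-applied at prediction).
#' @return A list of class `svr_config`.
#' @export
svr_config <- function(kernel = "radial", C = 100, epsilon = 1.0,
                       kernel_width_rule = c("scale", "dim"),
                       standardize = FALSE) {
  kernel_width_rule <- match.arg(kernel_width_rule)
  if (C <= 0) stop("C must be > 0")
  if (epsilon < 0) stop("epsilon must be >= 0")
  structure(list(kernel = kernel, C = C, epsilon = epsilon,
                 kernel_width_rule = kernel_width_rule,
                 standardize = standardize),
            class = "svr_config")
}

standardize_fit <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl)
}
standardize_apply <- function(x, st) {
  sweep(sweep(x, 2, st$center, "-"), 2, st$scale, "/")
}

#' Fit support vector regression on features
#'
#' @param features n x d feature matrix (e.g. from
#'   [extract_features()]).
#' @param tiller_counts integer response vector, length n, counts >= 0.
#' @param config an [svr_config()].
#' @return A `tiller_regressor` (method `"svr"`).
#' @export
fit_svr <- function(features, tiller_counts, config = svr_config()) {
  features <- as.matrix(features)
  y <- as.numeric(tiller_counts)
  if (nrow(features) != length(y))
    stop("features and tiller_counts have different numbers of samples")
  if (nrow(features) < 2) stop("need at least 2 samples")
  if (any(y < 0)) stop("tiller counts must be >= 0")
  st <- NULL
  x <- features
  if (config$standardize) {
    st <- standardize_fit(x)
    x <- standardize_apply(x, st)
  }
  d <- ncol(x)
  g <- if (config$kernel_width_rule == "scale") {
    v <- mean((x - mean(x))^2)
    if (v > 0) 1 / (d * v) else 1 / d
  } else 1 / d
  model <- e1071::svm(x = x, y = y, type = "eps-regression",
                      kernel = config$kernel, cost = config$C,
                      epsilon = config$epsilon, gamma = g,
                      scale = FALSE, fitted = FALSE)
  constant <- if (model$tot.nSV == 0) mean(y) else NULL
  structure(list(method = "svr", model = model, constant = constant,
                 config = config, standardizer = st,
                 feature_dim = ncol(features), fitted_on = nrow(features)),
            class = "tiller_regressor")
}

# Adam training of one affine head on fixed features (MSE loss).
# Features are standardized internally; the head is still one affine
# map end to end.
fit_head_on_features <- function(features, y, config = train_config(
                                   learning_rate = 0.01)) {
  x <- as.matrix(features)
  y <- as.numeric(y)
  n <- nrow(x); d <- ncol(x)
  if (n == 0) stop("empty label set")
  if (n != length(y)) stop("features and labels differ in length")
  if (config$batch_size > n)
    stop(sprintf("batch_size (%d) exceeds the training-set size (%d)",
                 config$batch_size, n))
  st <- standardize_fit(x)
  xs <- standardize_apply(x, st)
  w <- numeric(d); b <- mean(y)
  mw <- vw <- numeric(d); mb <- vb <- 0
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0
  lr <- config$learning_rate
  losses <- numeric(config$epochs)
  withr::with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      idx <- sample.int(n)
      acc <- 0
      for (off in seq(1, n, by = config$batch_size)) {
        bi <- idx[off:min(n, off + config$batch_size - 1)]
        xb <- xs[bi, , drop = FALSE]
        r <- drop(xb %*% w) + b - y[bi]
        acc <- acc + sum(r^2)
        gw <- 2 * drop(crossprod(xb, r)) / length(bi)
        gb <- 2 * sum(r) / length(bi)
        step <- step + 1
        corr <- lr * sqrt(1 - b2^step) / (1 - b1^step)
        mw <- b1 * mw + (1 - b1) * gw; vw <- b2 * vw + (1 - b2) * gw^2
        w <- w - corr * mw / (sqrt(vw) + eps)
        mb <- b1 * mb + (1 - b1) * gb; vb <- b2 * vb + (1 - b2) * gb^2
        b <- b - corr * mb / (sqrt(vb) + eps)
      }
      losses[ep] <- acc / n
    }
  })
  list(w = w, b = b, standardizer = st, loss = losses)
}

#' Fit a linear regression head with the backbone frozen
#'
#' Extracts features with the backbone in evaluation mode and trains a
#' single affine map (feature_dim -> 1) by mini-batch Adam under the
#' MSE loss.  The backbone parameters are read, never written: they
#' are bit-identical before and after the fit.
#'
#' @param backbone a `tiller_backbone` (left untouched).
#' @param images list of normalized images.
#' @param tiller_counts response vector.
#' @param config a [train_config()]; the default learning rate for
#'   head-only training is 0.01.
#' @return A `tiller_regressor` (method `"linear_head"`) that can
#'   predict from images (it carries the frozen backbone) or from
#'   feature matrices.
#' @export
fit_linear_head <- function(backbone, images, tiller_counts,
                            config = train_config(learning_rate = 0.01)) {
  if (length(tiller_counts) == 0) stop("empty label set")
  features <- extract_features(backbone, images)
  head <- fit_head_on_features(features, tiller_counts, config)
  structure(list(method = "linear_head", head = head,
                 backbone = backbone, config = config,
                 feature_dim = ncol(features), fitted_on = nrow(features)),
            class = "tiller_regressor")
}

#' Predict tiller numbers
#'
#' @param object a `tiller_regressor`.
#' @param newdata an n x feature_dim matrix, a single normalized image,
#'   or a list of normalized images (images require a regressor fitted
#'   through [fit_linear_head()], which carries its backbone).
#' @param ... unused.
#' @return One finite, continuous (unrounded) estimate per sample.
#' @export
predict.tiller_regressor <- function(object, newdata, ...) {
  if (is.list(newdata) || (is.array(newdata) && length(dim(newdata)) == 3)) {
    if (is.null(object$backbone))
      stop("this regressor was fitted on features; supply a feature matrix")
    newdata <- extract_features(object$backbone, newdata)
  }
  x <- as.matrix(newdata)
  if (ncol(x) != object$feature_dim)
    stop(sprintf("feature dimension %d does not match the fit (%d)",
                 ncol(x), object$feature_dim))
  if (object$method == "svr") {
    if (!is.null(object$constant)) return(rep(object$constant, nrow(x)))
    if (!is.null(object$standardizer))
      x <- standardize_apply(x, object$standardizer)
    unname(predict(object$model, x))
  } else {
    h <- object$head
    unname(drop(standardize_apply(x, h$standardizer) %*% h$w) + h$b)
  }
}

#' @export
print.tiller_regressor <- function(x, ...) {
  cat(sprintf("<tiller_regressor> method=%s, feature_dim=%d, fitted on %d samples\n",
              x$method, x$feature_dim, x$fitted_on))
  invisible(x)
}
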