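# Pretext-task construction and backbone training.
#
# A pretext task predicts an automatically computed trait (plant area
# or aspect ratio) from the normalized image, either as a continuous
# regression target (min-max scaled to [0,1]) or discretized into k
# equal-frequency classes.  The convolutional backbone is trained on
# the task under the standard protocol: 80/20 train/test split,
# mini-batch Adam, horizontal+vertical flip augmentation, several
# random restarts keeping the model with the lowest training error.

#' Build a pretext task specification
#'
#' For classification modes the bin edges are equal-frequency cuts of
#' the supplied trait pool: samples are stable-sorted by value and
#' dealt so that every class receives floor(n/k) or ceil(n/k) members
#' (ties may land in adjacent bins).  For regression the target is an
#' affine map of the trait range onto [0, 1].
#'
#' @param trait_values numeric trait pool (one value per unlabeled
#'   image), or a data frame from [segment_traits_table()].
#' @param trait `"area"` or `"aspect_ratio"` (used when a data frame is
#'   given, and recorded on the spec).
#' @param mode `"regression"` or `"classK"` (e.g. `"class4"`,
#'   `"class8"`; `"class1"` is a degenerate single-class task allowed
#'   for testing).
#' @return A list of class `pretext_task_spec` with `bin_edges`
#'   (classification; k-1 interior edges), `target_scaling`
#'   (regression), and the rank-based `labels` of the supplied pool.
#' @export
make_task_spec <- function(trait_values, trait = c("area", "aspect_ratio"),
                           mode = "regression") {
  trait <- match.arg(trait)
  if (is.data.frame(trait_values)) {
    col <- if (trait == "area") "area_px" else "aspect_ratio"
    trait_values <- trait_values[[col]][!trait_values$empty]
  }
  v <- as.numeric(trait_values)
  if (any(!is.finite(v))) stop("trait values must be finite")
  n <- length(v)
  if (mode == "regression") {
    lo <- min(v); hi <- max(v)
    if (hi <= lo) stop("regression task needs a non-degenerate trait range")
    sc <- list(offset = lo, scale = hi - lo)
    spec <- list(trait = trait, mode = mode, k = NA_integer_,
                 bin_edges = NULL, target_scaling = sc, n = n)
    spec$labels <- (v - lo) / (hi - lo)
  } else {
    k <- suppressWarnings(as.integer(sub("^class", "", mode)))
    if (is.na(k) || k < 1) stop("mode must be 'regression' or 'classK'")
    if (length(unique(v)) < k)
      stop(sprintf("need at least %d distinct trait values for %s", k, mode))
    ord <- order(v)                      # stable sort: ties keep input order
    lab_sorted <- floor((seq_len(n) - 1) * k / n)
    labels <- integer(n)
    labels[ord] <- lab_sorted
    vs <- v[ord]
    edges <- if (k > 1) vapply(seq_len(k - 1), function(j)
      vs[match(j, lab_sorted)], numeric(1)) else numeric(0)
    if (any(diff(edges) <= 0) && k > 2)
      edges <- sort(edges)  # duplicate-heavy pools; keep edges increasing
    spec <- list(trait = trait, mode = mode, k = k,
                 bin_edges = edges, target_scaling = NULL, n = n,
                 labels = labels)
  }
  structure(spec, class = "pretext_task_spec")
}

#' Assign a pretext label to a trait value
#'
#' Classification: index of the half-open bin `[edge_i, edge_{i+1})`,
#' with values equal to an interior edge going to the higher bin and
#' the last bin right-closed.  Regression: the affine-scaled value,
#' clipped to [0, 1] for out-of-range inputs.
#'
#' @param spec a [make_task_spec()] result.
#' @param trait_value numeric vector of trait values.
#' @return Class indices (0-based) or scaled targets.
#' @export
assign_label <- function(spec, trait_value) {
  v <- as.numeric(trait_value)
  if (any(!is.finite(v))) stop("trait value must be finite (no NaN/NA)")
  if (spec$mode == "regression") {
    clip01((v - spec$target_scaling$offset) / spec$target_scaling$scale)
  } else {
    if (spec$k == 1) return(rep(0L, length(v)))
    findInterval(v, spec$bin_edges)
  }
}

#' Backbone training configuration
#'
#' Defaults follow the standard protocol: mini-batch 128, learning
#' rate 1e-4, 200 epochs, 12 random restarts, 80/20 split, horizontal
#' and vertical flip augmentation.
#'
#' @param batch_size mini-batch size.
#' @param learning_rate Adam step size.
#' @param epochs training epochs per restart.
#' @param n_restarts independent restarts (seeds `seed + 0 ..
#'   seed + n_restarts - 1`); the restart with the lowest final
#'   training error is kept.
#' @param train_fraction fraction of the pool used for training.
#' @param augmentation subset of `c("horizontal_flip", "vertical_flip")`.
#' @param seed master seed for splitting, initialization, shuffling and
#'   augmentation.
#' @param architecture `"tiny"` (desk-scale; block-mean input pooling
#'   to 56 px, four conv blocks, one fully connected feature layer) or
#'   `"vgg16"` (full-size; 4096-d feature layer).
#' @param feature_width width of the tiny architecture's feature layer.
#' @return A list of class `train_config`.
#' @export
train_config <- function(batch_size = 128L, learning_rate = 1e-4,
                         epochs = 200L, n_restarts = 12L,
                         train_fraction = 0.8,
                         augmentation = c("horizontal_flip", "vertical_flip"),
                         seed = 0L, architecture = c("tiny", "vgg16"),
                         feature_width = 64L) {
  architecture <- match.arg(architecture)
  stopifnot(batch_size >= 1, epochs >= 1, n_restarts >= 1, feature_width >= 1)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  bad <- setdiff(augmentation, c("horizontal_flip", "vertical_flip"))
  if (length(bad) > 0) stop("unknown augmentation: ", paste(bad, collapse = ", "))
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 n_restarts = as.integer(n_restarts),
                 train_fraction = train_fraction,
                 augmentation = augmentation,
                 seed = as.integer(seed),
                 architecture = architecture,
                 feature_width = as.integer(feature_width)),
            class = "train_config")
}

# architecture descriptors consumed by the C++ engine -----------------------

conv_l <- function(out) list(kind = 1L, out = as.integer(out))
pool_l <- function() list(kind = 2L)
dense_l <- function(out) list(kind = 3L, out = as.integer(out))
head_l <- function(out) list(kind = 4L, out = as.integer(out))

backbone_arch <- function(architecture, feature_width = 64L, head_width = 1L) {
  if (architecture == "tiny") {
    list(channels = 3L, side = 56L, input_pool = 4L,
         layers = list(conv_l(8), pool_l(), conv_l(16), pool_l(),
                       conv_l(32), pool_l(), conv_l(32), pool_l(),
                       dense_l(feature_width), head_l(head_width)),
         feature_dim = as.integer(feature_width))
  } else if (architecture == "vgg16") {
    list(channels = 3L, side = 224L, input_pool = 1L,
         layers = c(list(conv_l(64), conv_l(64), pool_l(),
                         conv_l(128), conv_l(128), pool_l(),
                         conv_l(256), conv_l(256), conv_l(256), pool_l(),
                         conv_l(512), conv_l(512), conv_l(512), pool_l(),
                         conv_l(512), conv_l(512), conv_l(512), pool_l(),
                         dense_l(4096), dense_l(4096), head_l(head_width))),
         feature_dim = 4096L)
  } else stop("unknown architecture: ", architecture)
}

# flatten a list of normalized images into the engine's column layout,
# applying the architecture's block-mean input pooling.  A matrix whose
# row count already matches the engine input is passed through
# unchanged (streaming pipelines build it incrementally).
images_to_matrix <- function(images, arch) {
  if (is.matrix(images)) {
    if (nrow(images) != 3 * arch$side^2)
      stop("pre-built image matrix does not match the backbone input size")
    return(images)
  }
  if (is.array(images) && length(dim(images)) == 3) images <- list(images)
  side <- arch$side * arch$input_pool
  X <- vapply(images, function(im) {
    d <- dim(im)
    if (is.null(d) || d[1] != side || d[2] != side)
      stop(sprintf("image size %s does not match backbone input %d x %d",
                   paste(d[1:2], collapse = "x"), side, side))
    if (arch$input_pool > 1L) im <- cpp_block_mean(im, arch$input_pool)
    as.vector(im)
  }, numeric(3 * arch$side^2))
  matrix(X, nrow = 3 * arch$side^2)
}

new_backbone_obj <- function(architecture, arch, weights, provenance,
                             training_log = NULL, selected_restart = NA_integer_,
                             config = NULL) {
  structure(list(architecture = architecture, arch = arch, weights = weights,
                 feature_dim = arch$feature_dim,
                 input_side = arch$side * arch$input_pool,
                 provenance = provenance, training_log = training_log,
                 selected_restart = selected_restart, config = config),
            class = "tiller_backbone")
}

#' Create a randomly initialized backbone
#'
#' He-normal initialization; provenance `"random"`.  Serves as the
#' untrained control against which pretext-trained features are
#' compared.
#'
#' @param architecture `"tiny"` or `"vgg16"`.
#' @param seed initialization seed.
#' @param feature_width feature layer width of the tiny architecture.
#' @param head_width output width of the (untrained) head.
#' @return A `tiller_backbone`.
#' @export
new_backbone <- function(architecture = c("tiny", "vgg16"), seed = 0L,
                         feature_width = 64L, head_width = 1L) {
  architecture <- match.arg(architecture)
  arch <- backbone_arch(architecture, feature_width, head_width)
  w <- cpp_cnn_init(arch, as.integer(seed))
  new_backbone_obj(architecture, arch, w, "random")
}

#' Train a backbone on a pretext task
#'
#' Runs `n_restarts` independent trainings (differing only in seed:
#' weight initialization, shuffling and augmentation randomness) and
#' keeps the restart with the lowest final training error.  The 20%
#' held-out split is only logged, never used for selection.
#'
#' @param images list of normalized images (224 x 224 x 3 arrays).
#' @param trait_values trait value per image (pretext label source).
#' @param spec a [make_task_spec()].
#' @param config a [train_config()].
#' @param init optional `tiller_backbone` whose weights initialize
#'   every restart (e.g. externally supplied pretrained weights).
#' @return A `tiller_backbone` with provenance `"pretext:<trait>-<mode>"`
#'   and the full per-restart training log.
#' @export
train_backbone <- function(images, trait_values, spec, config = train_config(),
                           init = NULL) {
  if (length(images) == 0) stop("dataset is empty")
  labels <- assign_label(spec, trait_values)
  task <- if (spec$mode == "regression") 0L else 1L
  head_width <- if (task == 0L) 1L else spec$k
  arch <- backbone_arch(config$architecture, config$feature_width, head_width)
  X <- images_to_matrix(images, arch)
  n <- ncol(X)
  if (n != length(trait_values))
    stop("images and trait_values lengths differ")

  n_train <- floor(config$train_fraction * n)
  if (n_train < 1) stop("training split is empty")
  if (config$batch_size > n_train)
    stop(sprintf("batch_size (%d) exceeds the training-set size (%d)",
                 config$batch_size, n_train))
  perm <- withr::with_seed(config$seed, sample.int(n))
  train_idx <- perm[seq_len(n_train)]
  test_idx <- perm[-seq_len(n_train)]

  hflip <- "horizontal_flip" %in% config$augmentation
  vflip <- "vertical_flip" %in% config$augmentation

  restarts <- vector("list", config$n_restarts)
  finals <- numeric(config$n_restarts)
  for (r in seq_len(config$n_restarts)) {
    rseed <- config$seed + r - 1L
    w0 <- if (is.null(init)) cpp_cnn_init(arch, rseed) else init$weights
    res <- cpp_cnn_train(arch, w0, X, labels, train_idx, test_idx, task,
                         list(batch_size = config$batch_size,
                              learning_rate = config$learning_rate,
                              epochs = config$epochs, seed = rseed,
                              hflip = hflip, vflip = vflip))
    restarts[[r]] <- res
    finals[r] <- res$final_train_loss
  }
  best <- which.min(finals)
  log <- list(per_restart = lapply(restarts, function(r)
    list(epoch_loss = r$epoch_loss,
         final_train_loss = r$final_train_loss,
         final_test_loss = r$final_test_loss)),
    final_train_losses = finals)
  new_backbone_obj(config$architecture, arch, restarts[[best]]$weights,
                   paste0("pretext:", spec$trait, "-", spec$mode),
                   training_log = log, selected_restart = best,
                   config = config)
}

#' Save a backbone checkpoint with a JSON sidecar
#'
#' Weights go to `path` (RDS); a human-readable JSON sidecar at
#' `<path>.json` records architecture, feature dimensionality,
#' provenance, the training configuration and per-restart final losses.
#'
#' @param backbone a `tiller_backbone`.
#' @param path checkpoint file path.
#' @export
save_backbone <- function(backbone, path) {
  saveRDS(backbone, path)
  side <- list(architecture = backbone$architecture,
               feature_dim = backbone$feature_dim,
               provenance = backbone$provenance,
               selected_restart = backbone$selected_restart,
               config = backbone$config[
                 c("batch_size", "learning_rate", "epochs", "n_restarts",
                   "train_fraction", "seed", "architecture")],
               final_train_losses = backbone$training_log$final_train_losses)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Load a backbone checkpoint
#'
#' Externally supplied pretrained weights are accepted this way; the
#' provenance is relabelled `"external_pretrained"` unless the
#' checkpoint was written by [save_backbone()].
#'
#' @param path checkpoint file written by [save_backbone()].
#' @export
load_backbone <- function(path) {
  b <- readRDS(path)
  if (!inherits(b, "tiller_backbone")) stop("not a backbone checkpoint")
  b
}

#' @export
print.tiller_backbone <- function(x, ...) {
  cat(sprintf("<tiller_backbone> %s, feature_dim=%d, provenance=%s\n",
              x$architecture, x$feature_dim, x$provenance))
  invisible(x)
}
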