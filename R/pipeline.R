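# End-to-end orchestration on synthetic scenes: generate, normalize,
# segment, pretext-train, extract features, and compare tiller-count
# estimators under a shared cross-validation split.  All randomness
# flows from one top-level seed.

#' Regressor factories for cross-validation
#'
#' `head_factory` trains a fresh linear head (Adam, MSE) inside each
#' training fold; `svr_factory` fits SVR; `baseline_factory` refits
#' the two-covariate linear baseline (fresh weight from area via the
#' packaged refit constants as an affine proxy, plus aspect ratio) on
#' each training fold.  Predictions of the baseline are invariant to
#' which affine area-to-fresh-weight proxy is used.
#'
#' @param config a [train_config()] (head) or [svr_config()] (SVR).
#' @name regressor_factories
NULL

#' @rdname regressor_factories
#' @export
head_factory <- function(config = train_config(learning_rate = 0.01)) {
  function(train_x, train_y) {
    h <- fit_head_on_features(train_x, train_y, config)
    function(newdata)
      drop(standardize_apply(as.matrix(newdata), h$standardizer) %*% h$w) + h$b
  }
}

#' @rdname regressor_factories
#' @export
svr_factory <- function(config = svr_config()) {
  function(train_x, train_y) {
    reg <- fit_svr(train_x, train_y, config)
    function(newdata) predict(reg, as.matrix(newdata))
  }
}

#' @rdname regressor_factories
#' @export
baseline_factory <- function() {
  proxy <- baseline_coefficients("refit")
  function(train_x, train_y) {
    fw <- estimate_fresh_weight(train_x$area, proxy)
    rr <- refit_tiller_model(fw, train_x$aspect_ratio, train_y)
    function(newdata)
      estimate_tiller_count(estimate_fresh_weight(newdata$area, proxy),
                            newdata$aspect_ratio, rr$coefficients)
  }
}

#' Run the scaled-down estimation experiment on synthetic scenes
#'
#' Generates an unlabeled pool and a labeled set of synthetic scenes,
#' builds one normalization template per magnification group,
#' segments the normalized images for pretext labels and baseline
#' covariates, trains a tiny backbone on the area-regression pretext
#' task, and compares three estimators under the same k-fold split:
#' a linear head on pretext-trained features, the same head on
#' random-initialization features, and the refit linear baseline.
#'
#' @param seed top-level seed for every stage.
#' @param n_unlabeled size of the unlabeled pretext pool.
#' @param n_labeled number of scenes with tiller-count labels.
#' @param epochs,n_restarts,batch_size,learning_rate backbone training
#'   settings for the scaled run.
#' @param trait,mode pretext task (default area regression).
#' @param k cross-validation folds.
#' @param tiller_range tiller-count interval of the generator.
#' @param feature_width tiny-backbone feature width.
#' @param regress `"linear_head"` or `"svr"` for the feature-based
#'   estimators.
#' @return A list with per-method `cv_result`s (`cv`), the named
#'   `mae` vector, the trained backbone, and bookkeeping counts.
#' @export
run_tiller_experiment <- function(seed = 0L,
                                  n_unlabeled = 2000L, n_labeled = 600L,
                                  epochs = 20L, n_restarts = 2L,
                                  batch_size = 64L, learning_rate = 1e-3,
                                  trait = "area", mode = "regression",
                                  k = 6L, tiller_range = c(1L, 12L),
                                  feature_width = 64L,
                                  regress = c("linear_head", "svr")) {
  regress <- match.arg(regress)
  seed <- as.integer(seed)
  n_total <- n_unlabeled + n_labeled
  sconf <- scene_config()
  arch <- backbone_arch("tiny", feature_width, 1L)

  # stream the scenes chunkwise: render, normalize, segment, shrink to
  # the backbone's working resolution, then discard the full-size data
  scene_seeds <- withr::with_seed(seed, sample.int(2147483646L, n_total))
  gvec <- rep_len(1:3, n_total)
  X <- matrix(0, 3 * arch$side^2, n_total)
  counts_all <- integer(n_total)
  area <- aspect <- rep(NA_real_, n_total)
  empty <- logical(n_total)
  templates <- list()
  chunk <- 60L
  for (off in seq(1L, n_total, by = chunk)) {
    idx <- off:min(n_total, off + chunk - 1L)
    scenes <- lapply(idx, function(i) {
      sp <- generate_plant_spec(scene_seeds[i], tiller_range, gvec[i],
                                config = sconf)
      render_scene(sp, sconf)
    })
    for (sc in scenes) {
      g <- as.character(sc$magnification_group)
      if (is.null(templates[[g]]))
        templates[[g]] <- template_from_scene(sc)
    }
    nb <- batch_normalize(scenes, templates)
    tt <- segment_traits_table(nb$images)
    X[, idx] <- images_to_matrix(nb$images, arch)
    counts_all[idx] <- nb$manifest$tiller_count
    area[idx] <- tt$area_px
    aspect[idx] <- tt$aspect_ratio
    empty[idx] <- tt$empty
  }

  unl <- seq_len(n_unlabeled)
  lab <- n_unlabeled + seq_len(n_labeled)
  unl_ok <- unl[!empty[unl]]
  lab_ok <- lab[!empty[lab]]

  trait_values <- if (trait == "area") area else aspect
  spec <- make_task_spec(trait_values[unl_ok], trait = trait, mode = mode)
  cfg <- train_config(batch_size = batch_size, learning_rate = learning_rate,
                      epochs = epochs, n_restarts = n_restarts,
                      seed = seed, architecture = "tiny",
                      feature_width = feature_width)
  backbone <- train_backbone(X[, unl_ok, drop = FALSE], trait_values[unl_ok],
                             spec, cfg)
  random_bb <- new_backbone("tiny", seed = child_seed(seed, 977L),
                            feature_width = feature_width)

  counts <- counts_all[lab_ok]
  feats_p <- extract_features(backbone, X[, lab_ok, drop = FALSE])
  feats_r <- extract_features(random_bb, X[, lab_ok, drop = FALSE])
  covars <- data.frame(area = area[lab_ok], aspect_ratio = aspect[lab_ok])

  feat_factory <- if (regress == "linear_head") {
    head_factory(train_config(batch_size = min(128L, floor(length(lab_ok) *
                                                             (k - 1) / k)),
                              learning_rate = 0.01, epochs = 200L,
                              seed = seed))
  } else svr_factory()

  cv <- list(
    pretext = cross_validate(feats_p, counts, feat_factory, k = k, seed = seed,
                             method = paste0("pretext+", regress)),
    random = cross_validate(feats_r, counts, feat_factory, k = k, seed = seed,
                            method = paste0("random+", regress)),
    baseline = cross_validate(covars, counts, baseline_factory(), k = k,
                              seed = seed, method = "baseline"))
  list(cv = cv,
       mae = vapply(cv, `[[`, numeric(1), "mean_mae"),
       backbone = backbone,
       n_unlabeled_used = length(unl_ok),
       n_labeled_used = length(lab_ok),
       n_empty_dropped = n_total - length(unl_ok) - length(lab_ok))
}
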