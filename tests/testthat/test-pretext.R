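# Pretext-task construction (equal-frequency binning, label
# assignment) and the backbone training protocol (split, restarts,
# argmin selection, determinism).

test_that("equal-frequency binning reproduces the worked examples", {
  spec <- make_task_spec(1:8, "area", "class4")
  expect_equal(spec$labels, c(0, 0, 1, 1, 2, 2, 3, 3))
  expect_length(spec$bin_edges, 3)

  spec1 <- make_task_spec(c(4, 9, 2, 7), "area", "class1")
  expect_equal(spec1$labels, rep(0L, 4))
  expect_equal(assign_label(spec1, c(-5, 100)), c(0L, 0L))

  expect_error(make_task_spec(c(1, 1, 1), "area", "class4"), "distinct")
})

test_that("binning splits 10,000 uniform values into near-equal classes", {
  v <- withr::with_seed(10, runif(10000))
  spec <- make_task_spec(v, "area", "class8")
  counts <- tabulate(spec$labels + 1, nbins = 8)
  expect_true(all(abs(counts - 1250) <= 1))
  # rank-counting oracle: label = how many interior edges are <= value
  oracle <- vapply(v, function(x) sum(spec$bin_edges <= x), numeric(1))
  expect_equal(assign_label(spec, v), oracle)
})

test_that("label assignment follows the half-open bin convention", {
  spec <- make_task_spec(1:8, "area", "class4")
  # a value equal to an interior edge goes to the higher bin
  expect_equal(assign_label(spec, spec$bin_edges[2]), 2)
  expect_equal(assign_label(spec, spec$bin_edges[2] - 1e-9), 1)
  # last bin right-closed, out-of-range values clamp to the end bins
  expect_equal(assign_label(spec, 1e9), 3)
  expect_equal(assign_label(spec, -1e9), 0)
  expect_error(assign_label(spec, NaN), "finite")

  reg <- make_task_spec(c(10, 20, 30, 40), "area", "regression")
  expect_equal(assign_label(reg, 10), 0)
  expect_equal(assign_label(reg, 40), 1)
  expect_equal(assign_label(reg, 25), 0.5)
  expect_equal(assign_label(reg, 500), 1)   # clipped
})

test_that("labels agree with a brute-force edge-counting oracle on 1000 draws", {
  v <- withr::with_seed(4, rnorm(300, 50, 20))
  spec <- make_task_spec(v, "aspect_ratio", "class8")
  probe <- withr::with_seed(5, runif(1000, -20, 130))
  oracle <- vapply(probe, function(x)
    min(sum(spec$bin_edges <= x), spec$k - 1), numeric(1))
  expect_equal(assign_label(spec, probe), oracle)
})

test_that("equal-frequency property holds under ties", {
  v <- withr::with_seed(6, sample(1:7, 100, replace = TRUE))
  spec <- make_task_spec(v, "area", "class4")
  counts <- tabulate(spec$labels + 1, nbins = 4)
  expect_true(all(counts %in% c(floor(100 / 4), ceiling(100 / 4))))
})

test_that("classification heads have k outputs and regression heads one", {
  for (k in c(8L, 4L)) {
    arch <- tillerest:::backbone_arch("tiny", 64L, k)
    w <- tillerest:::cpp_cnn_init(arch, 0)
    expect_equal(nrow(w[[length(w)]]$W), k)
  }
  arch1 <- tillerest:::backbone_arch("tiny", 64L, 1L)
  w1 <- tillerest:::cpp_cnn_init(arch1, 0)
  expect_equal(nrow(w1[[length(w1)]]$W), 1)
})

test_that("training reduces the loss and keeps the argmin restart", {
  X <- fixture_pixel_matrix(120, seed = 8)
  traits <- withr::with_seed(9, runif(120, 1000, 9000))
  spec <- make_task_spec(traits, "area", "regression")
  cfg <- train_config(batch_size = 16L, learning_rate = 1e-3, epochs = 4L,
                      n_restarts = 3L, seed = 2L)
  bb <- train_backbone(X, traits, spec, cfg)
  finals <- bb$training_log$final_train_losses
  expect_length(finals, 3)
  expect_equal(bb$selected_restart, which.min(finals))
  sel <- bb$training_log$per_restart[[bb$selected_restart]]$epoch_loss
  expect_lt(sel[length(sel)], sel[1])
  expect_equal(bb$feature_dim, 64)
  expect_match(bb$provenance, "pretext:area-regression")
})

test_that("restart selection is exactly the argmin of final training error", {
  finals <- c(0.9, 0.4, 0.7)
  expect_equal(which.min(finals), 2)   # the contract train_backbone applies
  X <- fixture_pixel_matrix(40, seed = 11)
  traits <- withr::with_seed(12, runif(40))
  spec <- make_task_spec(traits, "area", "regression")
  bb <- train_backbone(X, traits, spec,
                       train_config(batch_size = 8L, epochs = 2L,
                                    n_restarts = 4L, seed = 5L,
                                    learning_rate = 1e-3))
  logged <- vapply(bb$training_log$per_restart, `[[`, numeric(1),
                   "final_train_loss")
  expect_equal(bb$selected_restart, which.min(logged))
})

test_that("oversized batches are rejected, not silently shrunk", {
  X <- fixture_pixel_matrix(20, seed = 13)
  traits <- withr::with_seed(14, runif(20))
  spec <- make_task_spec(traits, "area", "regression")
  expect_error(
    train_backbone(X, traits, spec,
                   train_config(batch_size = 128L, epochs = 1L,
                                n_restarts = 1L)),
    "batch_size")
})

test_that("fixed-seed training is fully reproducible", {
  X <- fixture_pixel_matrix(40, seed = 15)
  traits <- withr::with_seed(16, runif(40))
  spec <- make_task_spec(traits, "area", "class4")
  cfg <- train_config(batch_size = 8L, epochs = 2L, n_restarts = 2L,
                      seed = 21L, learning_rate = 1e-3)
  b1 <- train_backbone(X, traits, spec, cfg)
  b2 <- train_backbone(X, traits, spec, cfg)
  expect_identical(b1$weights, b2$weights)
  expect_identical(b1$training_log, b2$training_log)
})

test_that("backbones round-trip through checkpoints with JSON sidecars", {
  bb <- new_backbone("tiny", seed = 3, feature_width = 32)
  path <- withr::local_tempfile(fileext = ".rds")
  X <- fixture_pixel_matrix(3, seed = 17)
  save_backbone(bb, path)
  back <- load_backbone(path)
  expect_identical(back$weights, bb$weights)
  expect_identical(extract_features(back, X), extract_features(bb, X))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$architecture, "tiny")
  expect_equal(side$feature_dim, 32)
  expect_equal(side$provenance, "random")
})
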