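# Colour-threshold segmentation (union semantics) and trait
# computation, with the ground-truth masks of the generator as oracle.

test_that("pure white images give an empty mask", {
  img <- array(1, c(32, 32, 3))
  m <- segment_plant(img)
  expect_equal(sum(m), 0)
})

test_that("union semantics: one firing channel suffices", {
  img <- array(1, c(20, 20, 3))
  # saturated blue block: fires the saturation test only (a is
  # magenta-ward, b far below the yellow-ward interval)
  img[5:10, 5:10, 1] <- 0.1
  img[5:10, 5:10, 2] <- 0.1
  thr <- segmentation_thresholds(min_component_area = 0)
  m <- segment_plant(img, thr)
  expect_true(all(m[5:10, 5:10] == 1))
  expect_equal(sum(m), 36)
  # confirm it was saturation alone: disabling it empties the mask
  thr2 <- segmentation_thresholds(saturation = c(255, 255),
                                  min_component_area = 0)
  expect_equal(sum(segment_plant(img, thr2)), 0)
})

test_that("non-RGB input is rejected", {
  expect_error(segment_plant(matrix(1, 10, 10)), "H x W x 3")
})

test_that("widening any threshold interval never shrinks the mask", {
  sc <- fixture_scene(19, 1)
  tpl <- template_from_scene(sc)
  img <- apply_template(sc$image, tpl)
  base <- segmentation_thresholds(c(90, 255), c(0, 105), c(150, 255),
                                  min_component_area = 0)
  m0 <- segment_plant(img, base)
  wider <- list(
    segmentation_thresholds(c(60, 255), c(0, 105), c(150, 255), 0),
    segmentation_thresholds(c(90, 255), c(0, 118), c(150, 255), 0),
    segmentation_thresholds(c(90, 255), c(0, 105), c(135, 255), 0))
  for (thr in wider) {
    m1 <- segment_plant(img, thr)
    expect_true(all(m1[m0 == 1] == 1))
  }
})

test_that("8-bit colour conversions match the grDevices oracles", {
  px <- withr::with_seed(3, matrix(runif(300 * 3), ncol = 3))
  img <- array(c(px[, 1], px[, 2], px[, 3]), c(300, 1, 3))
  h8 <- tillerest:::cpp_rgb2hsv8(img)
  l8 <- tillerest:::cpp_rgb2lab8(img)
  o <- grDevices::rgb2hsv(t(px) * 255, maxColorValue = 255)
  expect_lte(max(abs(h8$s[, 1] - round(o[2, ] * 255))), 1)
  expect_lte(max(abs(h8$v[, 1] - round(o[3, ] * 255))), 1)
  lab <- grDevices::convertColor(px, from = "sRGB", to = "Lab")
  expect_lte(max(abs(l8$a[, 1] - round(lab[, 2] + 128))), 2)
  expect_lte(max(abs(l8$b[, 1] - round(lab[, 3] + 128))), 2)
})

test_that("segmentation recovers the generator's truth mask (IoU >= 0.90, 50 seeds)", {
  ious <- vapply(1:50, function(s) {
    sc <- render_scene(generate_plant_spec(s, c(1, 12), (s %% 3) + 1))
    tpl <- template_from_scene(sc)
    img <- apply_template(sc$image, tpl)
    truth <- apply_template(sc$truth_mask * 1.0, tpl, fill = 0) > 0.5
    m <- segment_plant(img) > 0
    sum(m & truth) / sum(m | truth)
  }, numeric(1))
  expect_gte(min(ious), 0.90)
})

test_that("traits match closed-form values on constructed masks", {
  m <- matrix(0L, 20, 20)
  m[3:12, 5:8] <- 1L                       # 10 rows x 4 cols
  tr <- compute_traits(m)
  expect_equal(tr$area, 40)
  expect_equal(tr$aspect_ratio, 2.5)

  m1 <- matrix(0L, 5, 5); m1[2, 2] <- 1L   # single pixel
  tr1 <- compute_traits(m1)
  expect_equal(tr1$area, 1)
  expect_equal(tr1$aspect_ratio, 1.0)

  m2 <- matrix(0L, 10, 12)
  m2[1, 1] <- 1L; m2[5, 10] <- 1L          # bbox 5 rows x 10 cols
  tr2 <- compute_traits(m2)
  expect_equal(tr2$area, 2)
  expect_equal(tr2$aspect_ratio, 0.5)

  expect_error(compute_traits(matrix(0L, 4, 4)), "empty segmentation")
})

test_that("mask area equals the direct pixel-count oracle", {
  sc <- fixture_scene(23, 1)
  tpl <- template_from_scene(sc)
  m <- segment_plant(apply_template(sc$image, tpl))
  expect_equal(compute_traits(m)$area, sum(m == 1))
})

test_that("flips leave area and aspect ratio unchanged", {
  sc <- fixture_scene(29, 1)
  tpl <- template_from_scene(sc)
  img <- apply_template(sc$image, tpl)
  tr <- compute_traits(segment_plant(img))
  himg <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
  vimg <- img[rev(seq_len(dim(img)[1])), , , drop = FALSE]
  trh <- compute_traits(segment_plant(himg))
  trv <- compute_traits(segment_plant(vimg))
  expect_equal(trh$area, tr$area)
  expect_equal(trv$area, tr$area)
  expect_equal(trh$aspect_ratio, tr$aspect_ratio)
  expect_equal(trv$aspect_ratio, tr$aspect_ratio)
})

test_that("small components are removed 8-connectedly", {
  img <- array(1, c(20, 20, 3))
  # large green block + a diagonal chain of green pixels
  green <- c(0.2, 0.8, 0.2)
  for (ch in 1:3) img[10:18, 10:18, ch] <- green[ch]
  for (k in 0:3) for (ch in 1:3) img[2 + k, 2 + k, ch] <- green[ch]
  thr <- segmentation_thresholds(min_component_area = 5)
  m <- segment_plant(img, thr)
  expect_equal(sum(m[1:6, 1:6]), 0)        # diagonal chain (4 px) removed
  expect_equal(sum(m[10:18, 10:18]), 81)   # block kept
  thr2 <- segmentation_thresholds(min_component_area = 4)
  m2 <- segment_plant(img, thr2)
  expect_equal(sum(m2[1:6, 1:6]), 4)       # 8-connected chain is one component
})
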