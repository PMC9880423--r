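# Pot-anchored normalization: template geometry, the 224 x 224 output
# contract, pot-size conservation and clip flagging.

test_that("template scale factor derives from the pot reference", {
  img <- array(1, c(200, 200, 3))
  tpl <- build_template(img, rect(0, 0, 200, 200), rect(50, 80, 60, 100))
  expect_equal(tpl$scale_factor, 0.32)          # 32 / 100 by hand
  tpl2 <- build_template(img, rect(0, 0, 200, 200), rect(50, 80, 60, 32))
  expect_equal(tpl2$scale_factor, 1.0)          # identity scale
})

test_that("invalid template geometry is rejected", {
  img <- array(1, c(100, 100, 3))
  expect_error(build_template(img, rect(10, 10, 50, 50), rect(40, 40, 30, 30)),
               "inside crop_rect")
  expect_error(build_template(img, rect(0, 0, 150, 100), rect(10, 10, 10, 10)),
               "outside the source")
  expect_error(rect(0, 0, 10, 0), "> 0")
})

test_that("normalized output is 224 x 224 with the pot at 32 px", {
  sc <- fixture_scene(13, 2)
  tpl <- template_from_scene(sc)
  out <- apply_template(sc$image, tpl)
  expect_equal(dim(out), c(224, 224, 3))
  pb <- transform_rect(tpl, sc$pot_bbox)
  expect_lt(abs(pb["h"] - 32), 1 + 1e-9)
  # pot centre lands on the horizontal centre, pot top at the anchor
  expect_equal(unname(pb["x"] + pb["w"] / 2), 112)
  expect_equal(unname(pb["y"]), 0.75 * 224)
})

test_that("padding outside the placed crop is white", {
  sc <- fixture_scene(13, 1)
  tpl <- template_from_scene(sc)
  out <- apply_template(sc$image, tpl)
  expect_white(out[1, 1, ])
  expect_white(out[1, 224, ])
  expect_white(out[224, 1, ])
  expect_white(out[224, 224, ])
})

test_that("identity template changes an already-normalized image at most marginally", {
  sc <- fixture_scene(13, 1)
  tpl <- template_from_scene(sc)
  norm <- apply_template(sc$image, tpl)
  # pot box in normalized coordinates defines an identity template
  idt <- build_template(norm, rect(0, 0, 224, 224),
                        rect(112 - 16, 168, 32, 32))
  expect_equal(idt$scale_factor, 1.0)
  twice <- apply_template(norm, idt)
  expect_lte(max(abs(twice - norm)), 2 / 255)
})

test_that("batch normalization preserves cardinality and is deterministic", {
  scenes <- lapply(1:10, function(s)
    render_scene(generate_plant_spec(100 + s, c(1, 6), (s %% 2) + 1)))
  tpls <- list("1" = template_from_scene(scenes[[2]]),
               "2" = template_from_scene(scenes[[1]]))
  nb <- batch_normalize(scenes, tpls)
  expect_length(nb$images, 10)
  expect_true(all(vapply(nb$images, function(im)
    all(dim(im) == c(224, 224, 3)), logical(1))))
  nb2 <- batch_normalize(scenes, tpls)
  expect_identical(nb$images, nb2$images)
  expect_error(batch_normalize(scenes, tpls["1"]), "no template")
})

test_that("plants cut by the crop rectangle are flagged", {
  sc <- fixture_scene(17, 1)
  # crop that keeps the pot but truncates the upper plant
  pb <- sc$pot_bbox
  crop <- rect(0, pb["y"] - 30, dim(sc$image)[2], 30 + pb["h"] + 8)
  tpl <- build_template(sc$image, crop, pb, magnification_group = 1L)
  nb <- batch_normalize(list(sc), list("1" = tpl))
  expect_true(nb$manifest$clipped[1])
  full <- batch_normalize(list(sc), list("1" = template_from_scene(sc)))
  expect_false(full$manifest$clipped[1])
})

test_that("templates round-trip through YAML", {
  sc <- fixture_scene(13, 2)
  tpl <- template_from_scene(sc)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_templates(list("2" = tpl), path)
  back <- read_templates(path)[["2"]]
  expect_equal(back$scale_factor, tpl$scale_factor, tolerance = 1e-12)
  expect_equal(back$crop_rect, tpl$crop_rect)
  expect_equal(back$tx, tpl$tx, tolerance = 1e-12)
  # applying the reread template reproduces the output to float precision
  expect_equal(apply_template(sc$image, back), apply_template(sc$image, tpl),
               tolerance = 1e-7)
})

test_that("extent mismatches raise a template-mismatch error", {
  sc <- fixture_scene(13, 1)
  tpl <- template_from_scene(sc)
  wrong <- array(1, c(100, 100, 3))
  expect_error(apply_template(wrong, tpl), "does not match")
})
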