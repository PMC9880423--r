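# Procedural generation of side-view potted-plant scenes.
#
# Each scene shows a single grass-like plant in a neutral grey pot on a
# near-white background.  The plant is a fan of quadratic-curve tillers
# with short leaf strokes, drawn in green hues so that the package's
# HSV/Lab thresholds can separate it from background and pot.  The
# ground-truth mask records exactly the plant pixels (never the pot),
# and the per-tiller area contribution is lognormally jittered so the
# area-count relation is learnable but not exact.

#' Scene rendering configuration
#'
#' @param canvas_w,canvas_h reference canvas size in pixels (before the
#'   magnification zoom is applied).
#' @param pot_w,pot_h pot size in pixels at reference magnification.
#' @param background_noise_sd standard deviation of the per-pixel
#'   Gaussian background noise on the [0,1] intensity scale.
#' @param area_jitter_sd lognormal sigma of the per-tiller length
#'   jitter; controls how noisy the area-to-tiller-count relation is.
#' @param stem_width,leaf_width stroke widths in pixels.
#' @param zoom_of_group integer zoom factor applied to the whole scene
#'   for each magnification group (pixel replication).
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(canvas_w = 280L, canvas_h = 320L,
                         pot_w = 80L, pot_h = 50L,
                         background_noise_sd = 3 / 255,
                         area_jitter_sd = 0.25,
                         stem_width = 6L, leaf_width = 5L,
                         zoom_of_group = c(1L, 2L, 3L)) {
  structure(list(canvas_w = as.integer(canvas_w), canvas_h = as.integer(canvas_h),
                 pot_w = as.integer(pot_w), pot_h = as.integer(pot_h),
                 background_noise_sd = background_noise_sd,
                 area_jitter_sd = area_jitter_sd,
                 stem_width = as.integer(stem_width),
                 leaf_width = as.integer(leaf_width),
                 zoom_of_group = as.integer(zoom_of_group)),
            class = "scene_config")
}

#' Draw a reproducible plant specification
#'
#' Samples the geometry of one synthetic plant: its tiller count
#' (uniform on `tiller_range`), one stem angle per tiller, plant height
#' and leaf parameters.  The result is fully determined by the inputs.
#'
#' @param seed integer seed; identical seeds and parameters give
#'   byte-identical specs.
#' @param tiller_range integer interval `c(lo, hi)`, bounds >= 1.
#' @param magnification_group small-integer group identifier (indexes
#'   `zoom_of_group` in [scene_config()]).
#' @param leaf_count_per_tiller leaves drawn along each tiller.
#' @param config a [scene_config()].
#' @return A list of class `plant_spec`.
#' @export
generate_plant_spec <- function(seed, tiller_range = c(1L, 12L),
                                magnification_group = 1L,
                                leaf_count_per_tiller = 3L,
                                config = scene_config()) {
  if (length(tiller_range) != 2 || any(!is.finite(tiller_range)))
    stop("tiller_range must be a finite integer interval c(lo, hi)")
  lo <- as.integer(tiller_range[1]); hi <- as.integer(tiller_range[2])
  if (lo > hi || lo < 1) stop("tiller_range must be non-empty with bounds >= 1")
  seed <- as.integer(seed)
  withr::with_seed(seed, {
    n <- lo + sample.int(hi - lo + 1L, 1L) - 1L
    base <- if (n == 1) 0 else seq(-28, 28, length.out = n)
    angles <- base + rnorm(n, 0, 4)
    height <- runif(1, 130, 230)
    curv <- runif(1, 0.2, 0.5)
  })
  structure(list(seed = seed,
                 tiller_count = n,
                 stem_angles = angles,
                 leaf_count_per_tiller = as.integer(leaf_count_per_tiller),
                 leaf_curvature = curv,
                 plant_height = height,
                 pot_width = config$pot_w,
                 pot_height = config$pot_h,
                 magnification_group = as.integer(magnification_group)),
            class = "plant_spec")
}

# dilate a polyline (x, y in 0-based pixel coords) with a disc brush;
# returns the covered pixel coordinates (may include out-of-canvas points)
disc_offsets <- function(width) {
  r <- max(0L, floor(width / 2))
  off <- expand.grid(dx = -r:r, dy = -r:r)
  off[off$dx^2 + off$dy^2 <= r^2 + 0.5, ]
}

stroke_pixels <- function(xs, ys, off) {
  list(px = round(rep(xs, each = nrow(off)) + off$dx),
       py = round(rep(ys, each = nrow(off)) + off$dy))
}

bezier2 <- function(p0, p1, p2, n) {
  t <- seq(0, 1, length.out = n)
  x <- (1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1]
  y <- (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2]
  cbind(x, y)
}

#' Render a plant specification into a scene
#'
#' Draws the pot and the green plant onto a near-white canvas, applies
#' the magnification-group zoom by pixel replication, and returns the
#' image together with the ground-truth plant mask (pot and background
#' excluded) and the pot bounding box.
#'
#' @param spec a [generate_plant_spec()] result.
#' @param config a [scene_config()].
#' @return A list of class `rendered_scene` with fields `image`
#'   (H x W x 3 array in [0,1]), `truth_mask` (0/1 integer matrix),
#'   `tiller_count`, `pot_bbox` (0-based half-open `c(x, y, w, h)`),
#'   `magnification_group` and `clipped` (TRUE when plant geometry hit
#'   the canvas border and was cut).
#' @export
render_scene <- function(spec, config = scene_config()) {
  if (!inherits(spec, "plant_spec")) stop("spec must be a plant_spec")
  g <- spec$magnification_group
  if (g < 1 || g > length(config$zoom_of_group))
    stop("magnification_group has no zoom factor in this scene_config")
  zoom <- config$zoom_of_group[g]
  H <- config$canvas_h; W <- config$canvas_w

  stem_off <- disc_offsets(config$stem_width)
  leaf_off <- disc_offsets(config$leaf_width)
  strokes <- list()   # each: list(px, py, col)

  withr::with_seed(child_seed(spec$seed, 101L), {
    bg <- 1 - abs(rnorm(H * W, 0, config$background_noise_sd))
    img <- array(rep(clip01(bg), 3), dim = c(H, W, 3))

    # pot: neutral grey block with a slight vertical shading, bottom-centred
    pot_x <- floor((W - spec$pot_width) / 2)
    pot_y <- H - 8L - spec$pot_height
    shade <- seq(0.50, 0.40, length.out = spec$pot_height)
    for (ch in 1:3) {
      base <- c(1.0, 0.98, 0.96)[ch]
      img[(pot_y + 1):(pot_y + spec$pot_height),
          (pot_x + 1):(pot_x + spec$pot_width), ch] <-
        matrix(shade * base, spec$pot_height, spec$pot_width)
    }

    bx <- W / 2; by <- pot_y
    for (i in seq_len(spec$tiller_count)) {
      theta <- spec$stem_angles[i] * pi / 180
      len <- spec$plant_height *
        exp(rnorm(1, 0, config$area_jitter_sd) - config$area_jitter_sd^2 / 2)
      dirv <- c(sin(theta), -cos(theta))
      perp <- c(cos(theta), sin(theta))
      p0 <- c(bx + runif(1, -6, 6), by)
      p2 <- p0 + len * dirv + perp * len * 0.1 * runif(1, -1, 1)
      p1 <- p0 + 0.55 * len * dirv +
        perp * len * 0.3 * spec$leaf_curvature * sample(c(-1, 1), 1)
      npts <- max(8L, ceiling(1.6 * len))
      pts <- bezier2(p0, p1, p2, npts)
      colv <- hsv(runif(1, 0.26, 0.34), runif(1, 0.80, 0.95), runif(1, 0.35, 0.55))
      colv <- as.vector(grDevices::col2rgb(colv)) / 255
      strokes[[length(strokes) + 1L]] <-
        c(stroke_pixels(pts[, 1], pts[, 2], stem_off), list(col = colv))

      for (j in seq_len(spec$leaf_count_per_tiller)) {
        f <- runif(1, 0.35, 0.95)
        anchor <- pts[max(1, round(f * npts)), ]
        side <- sample(c(-1, 1), 1)
        phi <- theta + side * runif(1, pi / 6, pi / 2.6)
        ld <- c(sin(phi), -cos(phi))
        ll <- runif(1, 0.15, 0.30) * len
        q2 <- anchor + ll * ld + c(0, 0.35 * ll)   # droop
        q1 <- anchor + 0.6 * ll * ld
        lpts <- bezier2(anchor, q1, q2, max(6L, ceiling(1.6 * ll)))
        lcol <- hsv(runif(1, 0.25, 0.33), runif(1, 0.80, 0.95), runif(1, 0.40, 0.60))
        lcol <- as.vector(grDevices::col2rgb(lcol)) / 255
        strokes[[length(strokes) + 1L]] <-
          c(stroke_pixels(lpts[, 1], lpts[, 2], leaf_off), list(col = lcol))
      }
    }
  })

  # paint all strokes in one vectorized pass (draw order preserved:
  # with duplicate indices the last assignment wins)
  px <- unlist(lapply(strokes, `[[`, "px"))
  py <- unlist(lapply(strokes, `[[`, "py"))
  cr <- unlist(lapply(strokes, function(s) rep(s$col[1], length(s$px))))
  cg <- unlist(lapply(strokes, function(s) rep(s$col[2], length(s$px))))
  cb <- unlist(lapply(strokes, function(s) rep(s$col[3], length(s$px))))
  inside <- px >= 0 & px < W & py >= 0 & py < H
  clipped <- any(!inside)
  i <- py[inside] + 1L; j <- px[inside] + 1L
  img[cbind(i, j, 1L)] <- cr[inside]
  img[cbind(i, j, 2L)] <- cg[inside]
  img[cbind(i, j, 3L)] <- cb[inside]
  mask <- matrix(0, H, W)
  mask[cbind(i, j)] <- 1
  if (zoom > 1L) {
    img <- cpp_zoom_nearest(img, zoom)
    mask <- cpp_zoom_nearest(mask, zoom)
  }
  structure(list(image = img,
                 truth_mask = matrix(as.integer(mask), nrow(mask), ncol(mask)),
                 tiller_count = spec$tiller_count,
                 pot_bbox = rect(pot_x * zoom, pot_y * zoom,
                                 spec$pot_width * zoom, spec$pot_height * zoom),
                 magnification_group = spec$magnification_group,
                 clipped = clipped),
            class = "rendered_scene")
}

#' Generate and render a batch of scenes
#'
#' Per-scene seeds are drawn from `seed`, and magnification groups are
#' cycled over `groups`, so a dataset mixes all magnifications.
#'
#' @param n number of scenes.
#' @param seed master seed.
#' @param tiller_range passed to [generate_plant_spec()].
#' @param groups magnification groups to cycle through.
#' @param config a [scene_config()].
#' @return A list of `rendered_scene` objects; per-scene specs are kept
#'   in the `"specs"` attribute.
#' @export
render_scene_batch <- function(n, seed = 0L, tiller_range = c(1L, 12L),
                               groups = 1:3, config = scene_config()) {
  seeds <- withr::with_seed(as.integer(seed), sample.int(2147483646L, n))
  gvec <- rep_len(as.integer(groups), n)
  specs <- lapply(seq_len(n), function(i)
    generate_plant_spec(seeds[i], tiller_range, gvec[i], config = config))
  scenes <- lapply(specs, render_scene, config = config)
  attr(scenes, "specs") <- specs
  scenes
}

#' Write scenes as paired PNG files plus a CSV manifest
#'
#' @param scenes a list of `rendered_scene` objects.
#' @param dir output directory (created if missing).
#' @return Invisibly, the manifest data frame (columns `scene_id`,
#'   `image_path`, `mask_path`, `tiller_count`, `magnification_group`,
#'   `pot_x`, `pot_y`, `pot_w`, `pot_h`, `clipped`).
#' @export
write_scene_set <- function(scenes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(scenes), function(i) {
    sc <- scenes[[i]]
    id <- sprintf("scene_%05d", i)
    ip <- file.path(dir, paste0(id, ".png"))
    mp <- file.path(dir, paste0(id, "_mask.png"))
    png::writePNG(sc$image, ip)
    png::writePNG(sc$truth_mask * 1.0, mp)
    data.frame(scene_id = id, image_path = ip, mask_path = mp,
               tiller_count = sc$tiller_count,
               magnification_group = sc$magnification_group,
               pot_x = sc$pot_bbox["x"], pot_y = sc$pot_bbox["y"],
               pot_w = sc$pot_bbox["w"], pot_h = sc$pot_bbox["h"],
               clipped = sc$clipped)
  })
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a scene set written by [write_scene_set()]
#'
#' @param dir directory containing `manifest.csv`.
#' @return A list of `rendered_scene` objects.
#' @export
read_scene_set <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    img <- png::readPNG(m$image_path)
    msk <- png::readPNG(m$mask_path)
    if (length(dim(msk)) == 3) msk <- msk[, , 1]
    structure(list(image = img,
                   truth_mask = matrix(as.integer(msk > 0.5), nrow(msk), ncol(msk)),
                   tiller_count = m$tiller_count,
                   pot_bbox = rect(m$pot_x, m$pot_y, m$pot_w, m$pot_h),
                   magnification_group = m$magnification_group,
                   clipped = m$clipped),
              class = "rendered_scene")
  })
}
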