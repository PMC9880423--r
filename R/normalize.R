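# Pot-anchored geometric normalization.
#
# One template per magnification group reproduces the semi-automatic
# recipe: crop a rectangle around the plant, rescale so the pot height
# equals `pot_target` pixels (32 by default), translate so the pot
# centre sits at the horizontal centre of the canvas with the pot top
# at a fixed vertical anchor, and pad with white to a square
# `output_side` x `output_side` (224 by default) image.  Resampling is
# a single fused crop+scale+translate pass with bicubic interpolation.

#' Normalization configuration
#'
#' @param output_side side of the square output canvas in pixels.
#' @param pot_target target pot size in the output, in pixels.
#' @param pot_dim which pot dimension is matched to `pot_target`:
#'   `"height"` (default; the dimension that is invariant in side
#'   views) or `"width"`.
#' @param anchor vertical position of the pot top in the output, as a
#'   fraction of `output_side` (plant above, pot below).
#' @return A list of class `norm_config`.
#' @export
norm_config <- function(output_side = 224L, pot_target = 32L,
                        pot_dim = c("height", "width"), anchor = 0.75) {
  pot_dim <- match.arg(pot_dim)
  if (anchor <= 0 || anchor >= 1) stop("anchor must be in (0, 1)")
  structure(list(output_side = as.integer(output_side),
                 pot_target = as.integer(pot_target),
                 pot_dim = pot_dim, anchor = anchor),
            class = "norm_config")
}

#' Build a normalization template from a sample image
#'
#' Records the crop rectangle, the pot reference box and the derived
#' scale factor (`pot_target / pot height`) for one magnification
#' group.  The same template is later applied to every image of that
#' group.
#'
#' @param sample_image RGB array (H x W x 3) the rectangles refer to.
#' @param crop_rect rectangle around the whole plant area, 0-based
#'   half-open `c(x, y, w, h)` in source pixels.
#' @param pot_bbox pot bounding box in the same (source) coordinates;
#'   must lie inside `crop_rect`.
#' @param magnification_group group identifier the template serves.
#' @param config a [norm_config()].
#' @return A list of class `norm_template` with the derived
#'   `scale_factor` and output translation.
#' @export
build_template <- function(sample_image, crop_rect, pot_bbox,
                           magnification_group = 1L, config = norm_config()) {
  assert_rgb(sample_image, "sample_image")
  crop_rect <- as_rect(crop_rect)
  pot_bbox <- as_rect(pot_bbox)
  if (!rect_inside(crop_rect, image_extent_rect(sample_image)))
    stop("crop_rect lies outside the source image extent")
  if (!rect_inside(pot_bbox, crop_rect))
    stop("pot_bbox must lie fully inside crop_rect")
  pot_extent <- if (config$pot_dim == "height") pot_bbox["h"] else pot_bbox["w"]
  if (pot_extent <= 0) stop("pot reference extent must be > 0")
  s <- config$pot_target / as.numeric(pot_extent)

  # pot box relative to the crop origin
  pot_in_crop <- rect(pot_bbox["x"] - crop_rect["x"],
                      pot_bbox["y"] - crop_rect["y"],
                      pot_bbox["w"], pot_bbox["h"])
  side <- config$output_side
  tx <- side / 2 - s * (pot_in_crop["x"] + pot_in_crop["w"] / 2)
  ty <- config$anchor * side - s * pot_in_crop["y"]
  structure(list(magnification_group = as.integer(magnification_group),
                 source_extent = dim(sample_image)[1:2],
                 crop_rect = crop_rect,
                 pot_bbox_in_crop = pot_in_crop,
                 scale_factor = unname(s),
                 tx = unname(tx), ty = unname(ty),
                 output_side = side,
                 pot_target = config$pot_target,
                 pot_dim = config$pot_dim,
                 anchor = config$anchor),
            class = "norm_template")
}

#' Build a template directly from a synthetic scene
#'
#' Uses the full scene extent as the crop rectangle and the scene's
#' known pot box as the pot reference.
#'
#' @param scene a `rendered_scene`.
#' @param config a [norm_config()].
#' @export
template_from_scene <- function(scene, config = norm_config()) {
  build_template(scene$image, image_extent_rect(scene$image), scene$pot_bbox,
                 magnification_group = scene$magnification_group,
                 config = config)
}

#' Map a source-coordinate rectangle through a template
#'
#' @param template a [build_template()] result.
#' @param r rectangle in source pixel coordinates.
#' @return The rectangle in output (normalized-image) coordinates.
#' @export
transform_rect <- function(template, r) {
  r <- as_rect(r)
  s <- template$scale_factor
  c(x = unname(s * (r["x"] - template$crop_rect["x"]) + template$tx),
    y = unname(s * (r["y"] - template$crop_rect["y"]) + template$ty),
    w = unname(s * r["w"]), h = unname(s * r["h"]))
}

#' Apply a normalization template to an image
#'
#' Crops, rescales (bicubic by default, with channel clipping), and
#' places the result on a white `output_side` x `output_side` canvas.
#'
#' @param image RGB array (H x W x 3) or single-channel matrix (e.g. a
#'   mask); its extent must match the template's source extent.
#' @param template a [build_template()] result.
#' @param interpolation `"bicubic"` or `"nearest"` (use nearest for
#'   binary masks).
#' @param fill padding value (white = 1 for images, 0 for masks).
#' @return The normalized raster with attribute `template_group`.
#' @export
apply_template <- function(image, template,
                           interpolation = c("bicubic", "nearest"),
                           fill = 1) {
  interpolation <- match.arg(interpolation)
  d <- dim(image)
  if (is.null(d) || !all(d[1:2] == template$source_extent))
    stop("image extent does not match the template's source extent")
  cr <- template$crop_rect
  out <- cpp_warp_affine(image, template$output_side, template$output_side,
                         template$scale_factor, template$tx, template$ty,
                         cr["x"], cr["y"], cr["w"], cr["h"],
                         fill, if (interpolation == "bicubic") 0L else 1L)
  attr(out, "template_group") <- template$magnification_group
  out
}

#' Normalize a batch of scenes
#'
#' Applies the matching magnification-group template to every scene,
#' transforms masks (when requested) with nearest-neighbour sampling,
#' and flags scenes whose plant pixels are cut by the crop rectangle or
#' the output canvas.
#'
#' @param scenes list of `rendered_scene` objects.
#' @param templates named list of templates, names = magnification
#'   group identifiers.
#' @param keep_masks also normalize the ground-truth masks.
#' @return A list with `images` (list of normalized arrays), `masks`
#'   (normalized 0/1 matrices or NULL), and a `manifest` data frame
#'   with the transformed pot boxes and a `clipped` flag.
#' @export
batch_normalize <- function(scenes, templates, keep_masks = FALSE) {
  images <- vector("list", length(scenes))
  masks <- if (keep_masks) vector("list", length(scenes)) else NULL
  rows <- vector("list", length(scenes))
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    tpl <- templates[[as.character(sc$magnification_group)]]
    if (is.null(tpl))
      stop(sprintf("no template for magnification group %s",
                   sc$magnification_group))
    images[[i]] <- apply_template(sc$image, tpl)
    clipped <- isTRUE(sc$clipped)
    if (!is.null(sc$truth_mask)) {
      idx <- which(sc$truth_mask > 0, arr.ind = TRUE)
      if (nrow(idx) > 0) {
        x <- idx[, 2] - 1; y <- idx[, 1] - 1
        cr <- tpl$crop_rect
        s <- tpl$scale_factor
        xo <- s * (x - cr["x"]) + tpl$tx
        yo <- s * (y - cr["y"]) + tpl$ty
        outside_crop <- any(x < cr["x"] | x >= cr["x"] + cr["w"] |
                              y < cr["y"] | y >= cr["y"] + cr["h"])
        outside_canvas <- any(xo < 0 | xo >= tpl$output_side |
                                yo < 0 | yo >= tpl$output_side)
        clipped <- clipped || outside_crop || outside_canvas
      }
      if (keep_masks) {
        m <- apply_template(sc$truth_mask, tpl, interpolation = "nearest", fill = 0)
        masks[[i]] <- matrix(as.integer(m > 0.5), nrow(m), ncol(m))
      }
    }
    pb <- transform_rect(tpl, sc$pot_bbox)
    rows[[i]] <- data.frame(scene_id = i, tiller_count = sc$tiller_count,
                            magnification_group = sc$magnification_group,
                            pot_x = pb["x"], pot_y = pb["y"],
                            pot_w = pb["w"], pot_h = pb["h"],
                            clipped = clipped)
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  list(images = images, masks = masks, manifest = manifest)
}

#' Serialize templates to a YAML file
#' @param templates named list of `norm_template` objects.
#' @param path output file.
#' @export
write_templates <- function(templates, path) {
  flat <- lapply(templates, function(t)
    list(magnification_group = t$magnification_group,
         source_extent = as.integer(t$source_extent),
         crop_rect = as.list(t$crop_rect),
         pot_bbox_in_crop = as.list(t$pot_bbox_in_crop),
         scale_factor = t$scale_factor, tx = t$tx, ty = t$ty,
         output_side = t$output_side, pot_target = t$pot_target,
         pot_dim = t$pot_dim, anchor = t$anchor))
  yaml::write_yaml(flat, path, precision = 15)
  invisible(path)
}

#' Read templates written by [write_templates()]
#' @param path YAML file.
#' @export
read_templates <- function(path) {
  flat <- yaml::read_yaml(path)
  lapply(flat, function(t) {
    structure(list(magnification_group = t$magnification_group,
                   source_extent = as.integer(unlist(t$source_extent)),
                   crop_rect = as_rect(unlist(t$crop_rect)),
                   pot_bbox_in_crop = as_rect(unlist(t$pot_bbox_in_crop)),
                   scale_factor = t$scale_factor, tx = t$tx, ty = t$ty,
                   output_side = t$output_side, pot_target = t$pot_target,
                   pot_dim = t$pot_dim, anchor = t$anchor),
              class = "norm_template")
  })
}
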