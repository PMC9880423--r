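# Colour-space plant segmentation and trait computation.
#
# The plant is separated from background and pot by thresholding the
# HSV saturation channel and the Lab a and b channels (8-bit scales,
# Lab a/b offset by 128) and taking the logical union of the three
# masks; connected components below a minimum area are then removed
# (8-connected).  From the final mask the two traits used throughout
# the package are computed: plant area (pixel count, A_sv) and aspect
# ratio (bounding-box height over width, HW).

#' Segmentation thresholds
#'
#' Inclusive intervals on the 8-bit channels.  The defaults are
#' calibrated for the synthetic scenes (green plant on near-white
#' background, grey pot): saturated pixels, green-ward a values, and
#' yellow-ward b values all vote for "plant".
#'
#' @param saturation inclusive interval on HSV saturation, 0..255.
#' @param a inclusive interval on the Lab a channel (offset by 128;
#'   values below 128 are green-ward).
#' @param b inclusive interval on the Lab b channel (offset by 128;
#'   values above 128 are yellow-ward).
#' @param min_component_area connected components (8-connected) smaller
#'   than this many pixels are discarded.
#' @return A list of class `segmentation_thresholds`.
#' @export
segmentation_thresholds <- function(saturation = c(90, 255),
                                    a = c(0, 105),
                                    b = c(150, 255),
                                    min_component_area = 10) {
  chk <- function(iv, nm) {
    if (length(iv) != 2 || iv[1] > iv[2] || iv[1] < 0 || iv[2] > 255)
      stop(sprintf("%s must be an inclusive interval within [0, 255]", nm))
  }
  chk(saturation, "saturation"); chk(a, "a"); chk(b, "b")
  if (min_component_area < 0) stop("min_component_area must be >= 0")
  structure(list(saturation = saturation, a = a, b = b,
                 min_component_area = min_component_area),
            class = "segmentation_thresholds")
}

#' Segment the plant in an RGB image
#'
#' @param image H x W x 3 numeric array in [0, 1].
#' @param thresholds a [segmentation_thresholds()].
#' @param source_id optional identifier carried on the mask.
#' @return A 0/1 integer matrix of class `plant_mask`.
#' @export
segment_plant <- function(image, thresholds = segmentation_thresholds(),
                          source_id = NULL) {
  assert_rgb(image)
  hsv8 <- cpp_rgb2hsv8(image)
  lab8 <- cpp_rgb2lab8(image)
  within <- function(m, iv) m >= iv[1] & m <= iv[2]
  m <- within(hsv8$s, thresholds$saturation) |
    within(lab8$a, thresholds$a) |
    within(lab8$b, thresholds$b)
  m <- matrix(as.integer(m), nrow(m), ncol(m))
  if (thresholds$min_component_area > 0 && any(m > 0)) {
    lab <- cpp_label8(m)
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes < thresholds$min_component_area)
    if (length(drop) > 0) m[lab %in% drop] <- 0L
  }
  structure(m, class = c("plant_mask", class(m)), source_id = source_id)
}

#' Compute area and aspect ratio of a plant mask
#'
#' Area is the count of set pixels; the aspect ratio is the height over
#' width of the tight bounding box of all set pixels (all surviving
#' components contribute to one joint box).
#'
#' @param mask binary matrix (e.g. from [segment_plant()]).
#' @return A list of class `trait_record` with `area`, `aspect_ratio`
#'   and `source_id`.
#' @export
compute_traits <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0)
    stop("empty segmentation: no plant pixels in mask", call. = FALSE)
  h <- diff(range(idx[, 1])) + 1
  w <- diff(range(idx[, 2])) + 1
  structure(list(area = nrow(idx), aspect_ratio = h / w,
                 source_id = attr(mask, "source_id")),
            class = "trait_record")
}

#' Segment a batch of images and tabulate their traits
#'
#' Images with an empty segmentation are kept in the table with NA
#' traits and `empty = TRUE`, so the caller decides to drop or flag.
#'
#' @param images list of RGB arrays.
#' @param thresholds a [segmentation_thresholds()].
#' @return A data frame with columns `source_id`, `area_px`,
#'   `aspect_ratio`, `empty`.
#' @export
segment_traits_table <- function(images, thresholds = segmentation_thresholds()) {
  ids <- names(images)
  if (is.null(ids)) ids <- as.character(seq_along(images))
  rows <- lapply(seq_along(images), function(i) {
    m <- segment_plant(images[[i]], thresholds, source_id = ids[i])
    if (!any(m > 0))
      return(data.frame(source_id = ids[i], area_px = NA_real_,
                        aspect_ratio = NA_real_, empty = TRUE))
    tr <- compute_traits(m)
    data.frame(source_id = ids[i], area_px = tr$area,
               aspect_ratio = tr$aspect_ratio, empty = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
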