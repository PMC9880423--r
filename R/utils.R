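# Shared helpers: rectangle convention and argument checks.
#
# Rectangles are length-4 named numeric vectors c(x, y, w, h) in 0-based,
# half-open pixel coordinates: the rect covers columns [x, x+w) and rows
# [y, y+h).  x runs along image columns (left to right), y along rows
# (top to bottom).

#' Construct a pixel rectangle
#'
#' @param x,y 0-based coordinates of the top-left corner.
#' @param w,h width and height in pixels (the rectangle is half-open).
#' @return A named numeric vector `c(x, y, w, h)`.
#' @export
rect <- function(x, y, w, h) {
  r <- c(x = as.numeric(x), y = as.numeric(y),
         w = as.numeric(w), h = as.numeric(h))
  if (any(!is.finite(r))) stop("rect: non-finite coordinates")
  if (r["w"] <= 0 || r["h"] <= 0) stop("rect: width and height must be > 0")
  r
}

as_rect <- function(r) {
  if (is.null(names(r))) names(r) <- c("x", "y", "w", "h")
  rect(r["x"], r["y"], r["w"], r["h"])
}

rect_inside <- function(inner, outer) {
  inner["x"] >= outer["x"] && inner["y"] >= outer["y"] &&
    inner["x"] + inner["w"] <= outer["x"] + outer["w"] &&
    inner["y"] + inner["h"] <= outer["y"] + outer["h"]
}

image_extent_rect <- function(img) {
  d <- dim(img)
  rect(0, 0, d[2], d[1])
}

assert_rgb <- function(img, what = "image") {
  d <- dim(img)
  if (is.null(d) || length(d) != 3 || d[3] != 3 || !is.numeric(img))
    stop(sprintf("%s must be an H x W x 3 numeric array", what))
  invisible(img)
}

# derive a well-spread child seed from a parent seed, kept below 2^31
child_seed <- function(seed, salt) {
  as.integer((as.double(seed) * 48271 + salt * 30269) %% 2147483647)
}

clip01 <- function(x) pmin(1, pmax(0, x))
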