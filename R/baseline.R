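# Conventional linear baseline: plant fresh weight is an affine
# function of the side-view plant area, and the tiller count an affine
# function of estimated fresh weight and aspect ratio.  The package
# ships both the originally published coefficients and the
# re-estimated ones for normalized images, and provides OLS refitting
# of either stage.
#
#   M_fw = fw_slope * A_sv + fw_intercept
#   TC   = tc_fw_coef * M_fw + tc_hw_coef * HW + tc_intercept

#' Packaged baseline coefficients
#'
#' `"published"` returns the original coefficients (fitted on
#' full-resolution images; their area scale does not transfer to
#' normalized images, which is why a refit path exists).  `"refit"`
#' returns the re-estimated coefficients for 224 x 224 pot-anchored
#' normalized images.
#'
#' @param provenance `"published"` or `"refit"`.
#' @return A list of class `baseline_coefficients` with fields
#'   `fw_slope` (g/px), `fw_intercept` (g), `tc_fw_coef` (tillers/g),
#'   `tc_hw_coef` (tillers per unit aspect ratio, stored with its
#'   sign), `tc_intercept` (tillers), `provenance`.
#' @export
baseline_coefficients <- function(provenance = c("published", "refit")) {
  provenance <- match.arg(provenance)
  if (provenance == "published") {
    new_baseline_coefficients(3.755e-5, -0.2704, 0.22, -2.19, 5.26, "published")
  } else {
    new_baseline_coefficients(0.005790, -0.3372, 0.1786, -1.1102, 3.885, "refit")
  }
}

new_baseline_coefficients <- function(fw_slope, fw_intercept, tc_fw_coef,
                                      tc_hw_coef, tc_intercept, provenance) {
  structure(list(fw_slope = fw_slope, fw_intercept = fw_intercept,
                 tc_fw_coef = tc_fw_coef, tc_hw_coef = tc_hw_coef,
                 tc_intercept = tc_intercept, provenance = provenance),
            class = "baseline_coefficients")
}

#' Estimate plant fresh weight from side-view area
#'
#' @param area plant area in pixels (>= 0); vectorized.
#' @param coeffs a [baseline_coefficients()].
#' @return Estimated fresh weight in grams (the affine model permits
#'   negative values for tiny areas).
#' @export
estimate_fresh_weight <- function(area, coeffs = baseline_coefficients()) {
  if (any(!is.finite(area)) || any(area < 0))
    stop("area must be finite and >= 0")
  coeffs$fw_slope * area + coeffs$fw_intercept
}

#' Estimate the tiller count from fresh weight and aspect ratio
#'
#' @param fresh_weight estimated fresh weight in grams; vectorized.
#' @param aspect_ratio plant bounding-box height over width.
#' @param coeffs a [baseline_coefficients()].
#' @return Continuous tiller-count estimate.
#' @export
estimate_tiller_count <- function(fresh_weight, aspect_ratio,
                                  coeffs = baseline_coefficients()) {
  if (any(!is.finite(fresh_weight)) || any(!is.finite(aspect_ratio)))
    stop("inputs must be finite")
  coeffs$tc_fw_coef * fresh_weight + coeffs$tc_hw_coef * aspect_ratio +
    coeffs$tc_intercept
}

r_squared <- function(y, fitted) {
  1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
}

#' Refit the fresh-weight model by ordinary least squares
#'
#' @param areas plant areas in pixels.
#' @param fresh_weights measured fresh weights in grams.
#' @return A list of class `refit_result` with `coefficients`
#'   (provenance `"refit"`; tiller-stage fields NA), `r_squared`
#'   (unadjusted, 1 - SS_res/SS_tot) and `n_samples`.
#' @export
refit_fresh_weight <- function(areas, fresh_weights) {
  if (length(areas) != length(fresh_weights)) stop("vectors differ in length")
  if (length(areas) < 3) stop("need at least 3 samples")
  if (var(areas) == 0) stop("singular fit: zero area variance")
  fit <- lm(fresh_weights ~ areas)
  co <- coef(fit)
  structure(list(coefficients = new_baseline_coefficients(
                   unname(co["areas"]), unname(co["(Intercept)"]),
                   NA_real_, NA_real_, NA_real_, "refit"),
                 r_squared = r_squared(fresh_weights, fitted(fit)),
                 n_samples = length(areas)),
            class = "refit_result")
}

#' Refit the two-covariate tiller-count model by ordinary least squares
#'
#' @param fresh_weights estimated fresh weights in grams.
#' @param aspect_ratios plant aspect ratios.
#' @param tiller_counts measured tiller counts.
#' @return A `refit_result`; the fresh-weight-stage fields of the
#'   coefficients are NA.
#' @export
refit_tiller_model <- function(fresh_weights, aspect_ratios, tiller_counts) {
  n <- length(tiller_counts)
  if (length(fresh_weights) != n || length(aspect_ratios) != n)
    stop("vectors differ in length")
  if (n < 4) stop("need at least 4 samples")
  X <- cbind(1, fresh_weights, aspect_ratios)
  if (qr(X)$rank < 3) stop("singular fit: collinear covariates")
  fit <- lm(tiller_counts ~ fresh_weights + aspect_ratios)
  co <- coef(fit)
  structure(list(coefficients = new_baseline_coefficients(
                   NA_real_, NA_real_,
                   unname(co["fresh_weights"]), unname(co["aspect_ratios"]),
                   unname(co["(Intercept)"]), "refit"),
                 r_squared = r_squared(tiller_counts, fitted(fit)),
                 n_samples = n),
            class = "refit_result")
}

#' @export
print.refit_result <- function(x, ...) {
  cat(sprintf("<refit_result> n=%d, R^2=%.4f\n", x$n_samples, x$r_squared))
  invisible(x)
}
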