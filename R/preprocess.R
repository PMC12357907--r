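# Image conditioning chain, applied in the canonical order:
# 8-bit conversion -> pseudo-flat-field -> median smoothing ->
# sliding-paraboloid background subtraction -> contrast enhancement.
# Channel routing (which channel receives which step) lives in the pipeline
# configuration; each operation records itself in the image provenance.

#' Convert an image to 8-bit by display-range (min-max) rescaling
#'
#' Values are linearly mapped from the image's own `[min, max]` to
#' `[0, 255]` and rounded half up. A constant image has zero dynamic range
#' and maps to all zeros.
#'
#' @param image a [channel_image()].
#' @return the converted [channel_image()], `bit_depth = 8`.
#' @export
to_8bit <- function(image) {
  px <- as_pixel_matrix(image)
  if (length(px) == 0) stop("empty image", call. = FALSE)
  lo <- min(px); hi <- max(px)
  out <- if (hi > lo) floor((px - lo) / (hi - lo) * 255 + 0.5)
  else matrix(0, nrow(px), ncol(px))
  img <- if (inherits(image, "channel_image")) image else
    channel_image(px, "DAPI")
  img$bit_depth <- 8L
  img_update(img, out, "to_8bit")
}

#' Pseudo-flat-field correction
#'
#' Divides the image by a heavily Gaussian-blurred copy of itself (the
#' estimated illumination field), then rescales so the mean grey value is
#' preserved. Output is clipped to `[0, 255]`.
#'
#' @param image a [channel_image()].
#' @param blur_radius_px Gaussian sigma of the illumination estimate, in
#'   pixels (default: image width / 3).
#' @return corrected [channel_image()].
#' @export
pseudo_flat_field <- function(image, blur_radius_px = NULL) {
  px <- as_pixel_matrix(image)
  if (is.null(blur_radius_px)) blur_radius_px <- ncol(px) / 3
  if (blur_radius_px < 1)
    stop("blur_radius_px must be >= 1", call. = FALSE)
  bg <- gauss_blur(px, blur_radius_px)
  eps <- 1e-6
  flat <- px / pmax(bg, eps)
  m <- mean(flat)
  out <- if (m > 0) flat * (mean(px) / m) else flat
  out <- pmin(pmax(out, 0), 255)
  img_update(image, out,
             sprintf("pseudo_flat_field(r=%.3g)", blur_radius_px))
}

#' Median smoothing over a disc neighbourhood
#'
#' @param image a [channel_image()].
#' @param radius_px disc radius in pixels (>= 1); borders are mirrored.
#' @return smoothed [channel_image()].
#' @export
median_smooth <- function(image, radius_px = 2) {
  if (radius_px < 1) stop("radius_px must be >= 1", call. = FALSE)
  px <- as_pixel_matrix(image)
  out <- cpp_median_disc(px, radius_px)
  img_update(image, out, sprintf("median_smooth(r=%.3g)", radius_px))
}

#' Sliding-paraboloid background subtraction
#'
#' Estimates the background as the grayscale opening of the intensity
#' surface with a paraboloid structuring element `z(d) = d^2 / (2 r)` —
#' equivalently, the envelope of a paraboloid of radius-of-curvature `r`
#' slid under the image — and subtracts it. Result is non-negative.
#'
#' @param image a [channel_image()].
#' @param radius_px paraboloid radius parameter in pixels (>= 1). Larger
#'   values remove only smoother, wider background.
#' @return background-subtracted [channel_image()].
#' @export
subtract_background_paraboloid <- function(image, radius_px = 50) {
  if (radius_px < 1) stop("radius_px must be >= 1", call. = FALSE)
  px <- as_pixel_matrix(image)
  bg <- cpp_paraboloid_background(px, radius_px)
  out <- pmax(px - bg, 0)
  img_update(image, out,
             sprintf("subtract_background_paraboloid(r=%.3g)", radius_px))
}

#' Linear contrast enhancement with saturation
#'
#' Maps the `saturated_fraction / 2` and `1 - saturated_fraction / 2`
#' intensity quantiles to 0 and 255 with clipping outside, so that a fixed
#' fraction of pixels saturates at each end.
#'
#' @param image a [channel_image()].
#' @param saturated_fraction total fraction of pixels allowed to saturate,
#'   in `[0, 0.5)`.
#' @return stretched [channel_image()].
#' @export
enhance_contrast <- function(image, saturated_fraction = 0.0035) {
  if (saturated_fraction < 0 || saturated_fraction >= 0.5)
    stop("saturated_fraction must be in [0, 0.5)", call. = FALSE)
  px <- as_pixel_matrix(image)
  if (min(px) == max(px)) {
    warning("constant image: contrast enhancement skipped")
    return(img_update(image, px, "enhance_contrast(skipped)"))
  }
  qs <- stats::quantile(px, c(saturated_fraction / 2,
                              1 - saturated_fraction / 2),
                        names = FALSE, type = 7)
  lo <- qs[1]; hi <- qs[2]
  if (hi <= lo) {  # extremely heavy-tailed histogram; fall back to min-max
    lo <- min(px); hi <- max(px)
  }
  out <- (px - lo) / (hi - lo) * 255
  out <- pmin(pmax(out, 0), 255)
  img_update(image, out,
             sprintf("enhance_contrast(sat=%.4g)", saturated_fraction))
}

#' Apply the canonical preprocessing chain with channel routing
#'
#' Routing defaults follow the reference protocol: pseudo-flat-field for MBP
#' and O4; median smoothing for all channels; paraboloid background
#' subtraction for O4 and DAPI; contrast enhancement for DAPI and O4.
#' The operations run in exactly this order; a different order requires
#' calling the individual operations explicitly.
#'
#' @param image a [channel_image()]; its `channel` field selects the routing.
#' @param params list of parameters (see [default_config()] section
#'   `preprocess`): `flat_field_radius` (NULL = width/3), `median_radius`,
#'   `paraboloid_radius`, `saturated_fraction`, and the routing vectors
#'   `flat_field_channels`, `background_channels`, `contrast_channels`.
#' @return preprocessed [channel_image()].
#' @export
preprocess_channel <- function(image, params = default_config()$preprocess) {
  ch <- image$channel
  img <- to_8bit(image)
  if (ch %in% params$flat_field_channels)
    img <- pseudo_flat_field(img, params$flat_field_radius)
  img <- median_smooth(img, params$median_radius)
  if (ch %in% params$background_channels)
    img <- subtract_background_paraboloid(img, params$paraboloid_radius)
  if (ch %in% params$contrast_channels)
    img <- enhance_contrast(img, params$saturated_fraction)
  img
}
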