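#' Single-channel fluorescence image
#'
#' The unit all preprocessing and segmentation operates on: a 2-D intensity
#' matrix plus the metadata the downstream stages need (channel label, pixel
#' size, bit depth) and a provenance log of every operation applied so far.
#'
#' @param pixels numeric matrix of intensities (rows x cols).
#' @param channel channel label, one of `"DAPI"`, `"O4"`, `"MBP"`.
#' @param pixel_size_um physical pixel size in micrometres per pixel.
#' @param bit_depth nominal bit depth of the stored intensities.
#' @param provenance character vector of operations already applied.
#' @return an object of class `channel_image`.
#' @export
channel_image <- function(pixels, channel = c("DAPI", "O4", "MBP"),
                          pixel_size_um = 1, bit_depth = 8,
                          provenance = character()) {
  channel <- match.arg(channel)
  if (!is.matrix(pixels) || length(pixels) == 0)
    stop("`pixels` must be a non-empty matrix", call. = FALSE)
  storage.mode(pixels) <- "double"
  structure(
    list(pixels = pixels, channel = channel,
         pixel_size_um = as.numeric(pixel_size_um),
         bit_depth = as.integer(bit_depth),
         provenance = as.character(provenance)),
    class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %s  %d x %d px  (%.3g um/px, %d-bit)\n",
              x$channel, nrow(x$pixels), ncol(x$pixels),
              x$pixel_size_um, x$bit_depth))
  rng <- range(x$pixels)
  cat(sprintf("  intensity range [%.4g, %.4g]\n", rng[1], rng[2]))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.channel_image <- function(x) dim(x$pixels)

# internal: return a copy with new pixels and one more provenance entry
img_update <- function(img, pixels, op) {
  img$pixels <- pixels
  img$provenance <- c(img$provenance, op)
  img
}

#' Binary segmentation mask
#'
#' @param pixels logical matrix.
#' @param source_channel channel label the mask was derived from.
#' @param threshold_used grey level of the threshold that produced it (or NA).
#' @return an object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, source_channel = "MBP", threshold_used = NA) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix", call. = FALSE)
  storage.mode(pixels) <- "logical"
  structure(list(pixels = pixels, source_channel = source_channel,
                 threshold_used = threshold_used),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> from %s  %d x %d px, %d foreground px",
              x$source_channel, nrow(x$pixels), ncol(x$pixels),
              sum(x$pixels)))
  if (!is.na(x$threshold_used))
    cat(sprintf("  (threshold %s)", format(x$threshold_used)))
  cat("\n")
  invisible(x)
}

as_pixel_matrix <- function(x) {
  if (inherits(x, "channel_image")) return(x$pixels)
  if (inherits(x, "binary_mask")) return(x$pixels)
  if (is.matrix(x)) return(x)
  stop("expected a matrix, channel_image or binary_mask", call. = FALSE)
}
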