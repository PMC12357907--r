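# Segmentation: Huang fuzzy-entropy thresholding (exhaustive and
# coarse-to-fine variants), binary mask clean-up (erode/open/dilate and
# distance-transform watershed), connected-component ROI extraction with
# convex-hull solidity, and the two bleed-through correction filters
# (solidity < 0.7, DAPI overlap < 60%).

# Huang & Wang's measure of fuzziness for every candidate threshold of a
# 256-bin histogram. Membership of grey g to its class is
# u = 1 / (1 + |g - mu_class| / C) with C the grey-level range; the score is
# the summed Shannon entropy of u. Returns a vector indexed by threshold t
# (foreground = grey > t), NA outside the searchable range.
huang_fuzziness <- function(counts) {
  g <- 0:255
  nz <- which(counts > 0) - 1L
  first <- min(nz); last <- max(nz)
  C <- last - first
  W <- cumsum(counts)
  S <- cumsum(counts * g)
  total_w <- W[256]; total_s <- S[256]
  out <- rep(NA_real_, 256)  # index t+1
  sf <- function(u) {
    v <- ifelse(u <= 0 | u >= 1, 0, -u * log(u) - (1 - u) * log(1 - u))
    v
  }
  for (t in first:(last - 1L)) {
    w0 <- W[t + 1]; s0 <- S[t + 1]
    mu0 <- s0 / w0
    mu1 <- (total_s - s0) / (total_w - w0)
    u <- ifelse(g <= t, 1 / (1 + abs(g - mu0) / C),
                1 / (1 + abs(g - mu1) / C))
    out[t + 1] <- sum(counts * sf(u)) / total_w
  }
  out
}

img_histogram <- function(px) {
  v <- pmin(pmax(round(px), 0), 255)
  tabulate(as.integer(v) + 1L, nbins = 256L)
}

#' Huang fuzzy-entropy threshold
#'
#' Selects the grey level minimising Huang's measure of fuzziness over the
#' 256-bin histogram; the mask keeps pixels strictly above the threshold.
#' `variant = "huang"` scans every candidate exhaustively; `"huang2"` is the
#' accelerated coarse-to-fine search over the same objective (step 8, then
#' refinement around the coarse optimum). Ties break to the lowest level.
#'
#' @param image a [channel_image()] (8-bit range expected).
#' @param variant `"huang"` or `"huang2"`.
#' @return list with `threshold` (grey level) and `mask`
#'   (a [binary_mask()]).
#' @export
huang_threshold <- function(image, variant = c("huang", "huang2")) {
  variant <- match.arg(variant)
  px <- as_pixel_matrix(image)
  counts <- img_histogram(px)
  nz <- which(counts > 0) - 1L
  if (length(nz) < 2)
    stop("degenerate histogram: image has < 2 distinct grey levels",
         call. = FALSE)
  fz <- huang_fuzziness(counts)
  cand <- which(!is.na(fz)) - 1L
  if (variant == "huang") {
    thr <- cand[which.min(fz[cand + 1])]
  } else {
    # coarse-to-fine: scan every 8th candidate, then refine around the best
    # few coarse minima (the fuzziness curve can be multi-basin)
    coarse <- cand[seq(1, length(cand), by = 8)]
    if (coarse[length(coarse)] != cand[length(cand)])
      coarse <- c(coarse, cand[length(cand)])
    best <- coarse[order(fz[coarse + 1])[seq_len(min(3, length(coarse)))]]
    fine <- sort(unique(unlist(lapply(best, function(t0)
      cand[cand >= t0 - 8 & cand <= t0 + 8]))))
    thr <- fine[which.min(fz[fine + 1])]
  }
  ch <- if (inherits(image, "channel_image")) image$channel else "MBP"
  list(threshold = as.integer(thr),
       mask = binary_mask(px > thr, source_channel = ch,
                          threshold_used = as.integer(thr)))
}

shift_mat <- function(m, di, dj, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  si <- max(1, 1 - di):min(nr, nr - di)
  sj <- max(1, 1 - dj):min(nc, nc - dj)
  out[si + di, sj + dj] <- m[si, sj]
  out
}

bin_erode3 <- function(m) {
  out <- m
  for (di in -1:1) for (dj in -1:1)
    if (di != 0 || dj != 0) out <- out & shift_mat(m, di, dj, FALSE)
  out
}

bin_dilate3 <- function(m) {
  out <- m
  for (di in -1:1) for (dj in -1:1)
    if (di != 0 || dj != 0) out <- out | shift_mat(m, di, dj, FALSE)
  out
}

max_filter3 <- function(m) {
  out <- m
  for (di in -1:1) for (dj in -1:1)
    if (di != 0 || dj != 0) out <- pmax(out, shift_mat(m, di, dj, -Inf))
  out
}

# distance-transform watershed: seeds at (smoothed) EDT maxima, flooding on
# the inverted EDT; watershed lines become background, splitting touching
# blobs
watershed_split <- function(m, min_seed_dist = 1.5) {
  if (!any(m)) return(m)
  dt <- sqrt(cpp_edt_sq(m))
  dtb <- gauss_blur(dt, 1)
  maxima <- m & dt >= min_seed_dist & dtb >= max_filter3(dtb) - 1e-9
  if (!any(maxima)) return(m)
  markers <- cpp_label(maxima, 8L)
  lab <- cpp_watershed(-dt, markers, m)
  lab > 0
}

#' Apply a sequence of binary operations to a mask
#'
#' `erode`, `open` and `dilate` use a 3 x 3 square structuring element, one
#' iteration each; `watershed` splits touching blobs by flooding the inverted
#' Euclidean distance transform from its regional maxima (the split lines
#' become background).
#'
#' @param mask a [binary_mask()].
#' @param ops character vector, ordered subset of
#'   `c("erode", "open", "dilate", "watershed")` (repeats allowed).
#' @return the processed [binary_mask()].
#' @export
apply_binary_ops <- function(mask, ops) {
  if (length(ops) == 0) stop("ops must be non-empty", call. = FALSE)
  bad <- setdiff(ops, c("erode", "open", "dilate", "watershed"))
  if (length(bad))
    stop("unknown binary op(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  m <- mask$pixels
  for (op in ops) {
    m <- switch(op,
                erode = bin_erode3(m),
                open = bin_dilate3(bin_erode3(m)),
                dilate = bin_dilate3(m),
                watershed = watershed_split(m))
  }
  binary_mask(m, mask$source_channel, mask$threshold_used)
}

# number of lattice points inside (or on) the convex hull of integer points
hull_pixel_count <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n <= 2) return(n)
  h <- grDevices::chull(pts[, 2], pts[, 1])  # (x, y); returns clockwise
  if (length(h) <= 2) {
    # collinear set: hull degenerates to a segment; for pixel sets this can
    # only be a 1-px-wide line, all of whose pixels are the set itself
    return(n)
  }
  V <- pts[h, , drop = FALSE]  # (y, x) vertices
  i0 <- min(pts[, 1]); i1 <- max(pts[, 1])
  j0 <- min(pts[, 2]); j1 <- max(pts[, 2])
  gy <- rep(i0:i1, times = j1 - j0 + 1)
  gx <- rep(j0:j1, each = i1 - i0 + 1)
  k <- nrow(V)
  # polygon orientation from the shoelace sum (coordinates are exact ints)
  xs <- V[, 2]; ys <- V[, 1]
  xn <- xs[c(2:k, 1)]; yn <- ys[c(2:k, 1)]
  sgn <- sign(sum(xs * yn - xn * ys))
  if (sgn == 0) return(n)
  inside <- rep(TRUE, length(gy))
  for (e in seq_len(k)) {
    a <- V[e, ]; b <- V[if (e == k) 1 else e + 1, ]
    cr <- (b[2] - a[2]) * (gy - a[1]) - (b[1] - a[1]) * (gx - a[2])
    inside <- inside & (sgn * cr >= -1e-9)
  }
  sum(inside)
}

#' Extract labelled ROIs from a binary mask
#'
#' 8-connected components with at least `min_area_px` pixels; each ROI
#' carries area (px and um^2), centroid, bounding box and solidity
#' (pixel count / pixel count of its convex hull).
#'
#' @param mask a [binary_mask()].
#' @param min_area_px minimum component area in pixels (>= 1).
#' @param pixel_size_um pixel size used for `area_um2`.
#' @return list of ROIs (class `roi_set`) with the mask shape as attribute.
#' @export
extract_rois <- function(mask, min_area_px = 20, pixel_size_um = 1) {
  if (min_area_px < 1) stop("min_area_px must be >= 1", call. = FALSE)
  m <- mask$pixels
  lab <- cpp_label(m, 8L)
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  rois <- list()
  coords <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[coords]
  for (id in ids) {
    pts <- coords[labs == id, , drop = FALSE]
    if (nrow(pts) < min_area_px) next
    colnames(pts) <- NULL
    hull_n <- hull_pixel_count(pts)
    rois[[length(rois) + 1]] <- list(
      label = length(rois) + 1L,
      pixels = pts,
      area_px = nrow(pts),
      area_um2 = nrow(pts) * pixel_size_um^2,
      centroid = c(mean(pts[, 1]), mean(pts[, 2])),
      bbox = c(min(pts[, 1]), min(pts[, 2]), max(pts[, 1]), max(pts[, 2])),
      solidity = nrow(pts) / hull_n)
  }
  structure(rois, shape = dim(m), pixel_size_um = pixel_size_um,
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d ROIs", length(x)))
  if (length(x))
    cat(sprintf("  (areas %d-%d px, solidity %.2f-%.2f)",
                min(vapply(x, `[[`, numeric(1), "area_px")),
                max(vapply(x, `[[`, numeric(1), "area_px")),
                min(vapply(x, `[[`, numeric(1), "solidity")),
                max(vapply(x, `[[`, numeric(1), "solidity"))))
  cat("\n")
  invisible(x)
}

keep_rois <- function(rois, keep) {
  structure(rois[keep], shape = attr(rois, "shape"),
            pixel_size_um = attr(rois, "pixel_size_um"), class = "roi_set")
}

#' Retain only low-solidity (branched) ROIs
#'
#' Keeps ROIs with solidity strictly below the cut-off; compact blobs
#' (nuclear bleed-through, solidity near 1) are removed. Strict inequality:
#' solidity exactly at the cut-off is removed. Idempotent.
#'
#' @param rois a `roi_set` from [extract_rois()].
#' @param max_solidity cut-off (default 0.7).
#' @return filtered `roi_set`, order preserved.
#' @export
filter_by_solidity <- function(rois, max_solidity = 0.7) {
  sol <- vapply(rois, `[[`, numeric(1), "solidity")
  keep_rois(rois, sol < max_solidity)
}

#' Remove target ROIs overlapping reference-channel ROIs
#'
#' For each target (marker-channel) ROI the overlap fraction is the share of
#' its own pixels lying inside the union of the reference (DAPI) ROIs; ROIs
#' with overlap strictly below `max_overlap` are kept. Strict inequality:
#' exactly 60% overlap is removed. Idempotent.
#'
#' @param target_rois,reference_rois `roi_set`s from images of identical
#'   shape.
#' @param max_overlap cut-off fraction (default 0.6).
#' @return filtered target `roi_set`; each kept ROI gains an
#'   `overlap_fraction` field.
#' @export
filter_bleedthrough <- function(target_rois, reference_rois,
                                max_overlap = 0.6) {
  shp_t <- attr(target_rois, "shape")
  shp_r <- attr(reference_rois, "shape")
  if (is.null(shp_t) || is.null(shp_r) || !identical(shp_t, shp_r))
    stop("ROI sets come from images of different shape", call. = FALSE)
  ref <- matrix(FALSE, shp_t[1], shp_t[2])
  for (r in reference_rois) ref[r$pixels] <- TRUE
  ov <- vapply(target_rois, function(r) sum(ref[r$pixels]) / r$area_px,
               numeric(1))
  out <- keep_rois(target_rois, ov < max_overlap)
  kept_ov <- ov[ov < max_overlap]
  for (k in seq_along(out)) out[[k]]$overlap_fraction <- kept_ov[k]
  out
}

#' Union mask of a ROI set
#'
#' @param rois a `roi_set`.
#' @param source_channel label for the resulting mask.
#' @return a [binary_mask()] covering exactly the ROI pixels.
#' @export
roi_union_mask <- function(rois, source_channel = "MBP") {
  shp <- attr(rois, "shape")
  m <- matrix(FALSE, shp[1], shp[2])
  for (r in rois) m[r$pixels] <- TRUE
  binary_mask(m, source_channel)
}

#' ROI set as a data frame
#'
#' @param rois a `roi_set`.
#' @return data.frame with label, areas, centroid, solidity and (if the
#'   bleed-through filter ran) overlap fraction.
#' @export
rois_to_df <- function(rois) {
  if (length(rois) == 0)
    return(data.frame(label = integer(), area_px = integer(),
                      area_um2 = numeric(), centroid_row = numeric(),
                      centroid_col = numeric(), solidity = numeric(),
                      overlap_fraction = numeric()))
  data.frame(
    label = vapply(rois, `[[`, integer(1), "label"),
    area_px = vapply(rois, function(r) as.integer(r$area_px), integer(1)),
    area_um2 = vapply(rois, `[[`, numeric(1), "area_um2"),
    centroid_row = vapply(rois, function(r) r$centroid[1], numeric(1)),
    centroid_col = vapply(rois, function(r) r$centroid[2], numeric(1)),
    solidity = vapply(rois, `[[`, numeric(1), "solidity"),
    overlap_fraction = vapply(rois, function(r)
      if (is.null(r$overlap_fraction)) NA_real_ else r$overlap_fraction,
      numeric(1)))
}
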